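test_that("generation is byte-identical under a fixed seed", {
  d <- small_design(seed = 11)
  t1 <- generate_toy_genome(d)
  t2 <- generate_toy_genome(d)
  expect_identical(as.character(t1$genome), as.character(t2$genome))
  expect_identical(t1$planted, t2$planted)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_gene_annotation(t1$annotation, f1)
  write_gene_annotation(t2$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))

  c1 <- simulate_junction_counts(t1)
  c2 <- simulate_junction_counts(t2)
  expect_identical(c1$counts$counts, c2$counts$counts)
  e1 <- simulate_cell_expression(t1)
  e2 <- simulate_cell_expression(t2)
  expect_identical(e1$expr, e2$expr)
})

test_that("every junction, annotated or planted, is GT/AG", {
  toy <- generate_toy_genome(small_design())
  jall <- rbind(
    annotation_junctions(toy$annotation)[, -1],
    toy$planted[, c("chrom", "intron_start", "intron_end", "strand",
                    "gene_id")])
  dn <- t(vapply(seq_len(nrow(jall)), function(i)
    splice_site_dinucleotides(jall[i, ], toy$genome), c("", "")))
  expect_true(all(dn[, 1] == "GT"))
  expect_true(all(dn[, 2] == "AG"))
})

test_that("generated annotation satisfies the model invariants", {
  toy <- generate_toy_genome(small_design())
  for (m in toy$annotation) {
    ex <- m$exons
    expect_true(all(ex[, 2] > ex[, 1]))
    if (nrow(ex) > 1) expect_true(all(ex[-1, 1] >= ex[-nrow(ex), 2]))
    expect_false(is.na(m$cds_start))
    expect_equal((m$cds_end - m$cds_start) %% 3, 0)
    # clean reading frame: ATG start, terminal stop, no internal stop
    s <- extract_transcript_sequence(m, toy$genome)
    cds <- substring(s, m$cds_start + 1, m$cds_end)
    expect_equal(substring(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds), 3),
                        seq(3, nchar(cds), 3))
    expect_true(tail(codons, 1) %in% c("TAA", "TAG", "TGA"))
    expect_false(any(head(codons, -1) %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("design validation rejects impossible settings", {
  expect_error(cohort_design(), "seed")
  expect_error(cohort_design(seed = 1, carrier_fraction = 0),
               "carrier_fraction")
  expect_error(cohort_design(seed = 1, marker_pct_lo = 0.9,
                             marker_pct_hi = 0.5), "pct_lo")
  expect_error(cohort_design(seed = 1, delta_psi = 0.999), "delta_psi")
  expect_error(cohort_design(seed = 1,
                             event_mix = c(cryptic_ss = 1, exon_skip = 1,
                                           utr3 = 1)), "event_mix")
})

test_that("zero genes yields an empty annotation but a valid genome", {
  d <- small_design()
  d$n_genes <- 0
  toy <- generate_toy_genome(d)
  expect_length(toy$annotation, 0)
  expect_gt(sum(Biostrings::width(toy$genome)), 0)
})

test_that("planted aberrant junctions are near-absent in controls", {
  for (seed in c(3, 13, 23)) {
    co <- simulate_junction_counts(generate_toy_genome(small_design(seed)))
    psi <- compute_psi(co$counts)
    ctl <- psi$metadata$sample[psi$metadata$group == "control"]
    ab <- co$truth$junction_id[startsWith(co$truth$class, "aberrant_up")]
    med <- apply(psi$psi[ab, ctl, drop = FALSE], 1, median, na.rm = TRUE)
    expect_true(all(med < 0.05))
  }
})

test_that("a zero-effect design leaves case and control PSI alike", {
  d <- small_design(seed = 5)
  d$delta_psi <- 0
  d$normal_shift <- 0
  co <- simulate_junction_counts(generate_toy_genome(d))
  psi <- compute_psi(co$counts)
  meta <- psi$metadata
  ab <- co$truth$junction_id[startsWith(co$truth$class, "aberrant_up")]
  cs <- psi$psi[ab, meta$sample[meta$group == "ALS"], drop = FALSE]
  ct <- psi$psi[ab, meta$sample[meta$group == "control"], drop = FALSE]
  # pooled means should agree within the Beta's sampling noise
  expect_lt(abs(mean(cs, na.rm = TRUE) - mean(ct, na.rm = TRUE)), 0.01)
})

test_that("composition shifts lower the target type in the disease group", {
  co <- shared_cohort()
  comp <- composition_summary(co$cells)
  pg <- comp$per_group
  oligo <- function(g) pg$median[pg$group == g &
                                   pg$cell_type == "Oligodendrocyte"]
  neuron <- function(g) pg$median[pg$group == g & pg$cell_type == "Neuron"]
  expect_lt(oligo("ALS"), oligo("control"))
  expect_lt(neuron("FTD"), neuron("control"))
})

test_that("peak placement probabilities are honoured", {
  toy <- generate_toy_genome(small_design())
  ab <- toy$planted[startsWith(toy$planted$class, "aberrant_up"), ]
  lens <- setNames(Biostrings::width(toy$genome), names(toy$genome))
  forced <- simulate_peaks(ab, lens, c(X = 1), background_peaks = 0,
                           seed = 9)
  expect_equal(binding_fraction(ab, forced)$fraction, 1.0)
  none <- simulate_peaks(ab, lens, c(X = 0), background_peaks = 0,
                         seed = 9)
  expect_equal(nrow(none$X$peaks), 0L)

  # intermediate probability: binomial 99% CI over many junctions
  many <- do.call(rbind, replicate(40, ab, simplify = FALSE))
  many$intron_start <- many$intron_start +
    rep(seq(0, 39) * 50000L, each = nrow(ab))
  many$intron_end <- many$intron_end +
    rep(seq(0, 39) * 50000L, each = nrow(ab))
  many$junction_id <- junction_id(many$chrom, many$intron_start,
                                  many$intron_end, many$strand)
  half <- simulate_peaks(many, lens + 3e6, c(X = 0.5),
                         background_peaks = 0, seed = 10)
  fr <- binding_fraction(many, half)$fraction
  n <- nrow(many)
  ci <- 2.576 * sqrt(0.25 / n)
  expect_gt(fr, 0.5 - ci)
  expect_lt(fr, 0.5 + ci)
})

test_that("cohort files round-trip through the readers", {
  co <- memo("small_cohort", simulate_cohort(small_design()))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_junction_counts(file.path(dir, "junction_counts.tsv"),
                               file.path(dir, "sample_metadata.tsv"))
  expect_equal(back$counts, co$counts$counts)
  genome <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(as.character(genome), as.character(co$genome))
  ann <- read_gene_annotation(file.path(dir, "annotation.gtf"))
  m0 <- co$annotation[[1]]
  expect_equal(ann[[m0$transcript_id]]$exons, m0$exons)
  expect_equal(ann[[m0$transcript_id]]$cds_start, m0$cds_start)
})
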