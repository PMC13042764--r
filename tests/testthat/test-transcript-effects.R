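# three-exon toy: exons (0,100), (200,300), (400,500) on a 600-nt chrom
toy_model <- function(strand = "+", genome_seed = 3) {
  set.seed(genome_seed)
  chr <- random_seq(600)
  list(model = transcript_model("t1", "g1", "chrT", strand,
                                rbind(c(0, 100), c(200, 300),
                                      c(400, 500))),
       genome = c(chrT = chr))
}

test_that("reconstruction keeps annotated introns that touch the event", {
  tm <- toy_model()
  j1 <- splice_junctions("chrT", 100, 250, "+")[1, ]
  ab1 <- reconstruct_aberrant_transcript(tm$model, j1, tm$genome)
  expect_equal(unname(ab1$exon_chain),
               matrix(c(0, 250, 400, 100, 300, 500), ncol = 2))
  expect_equal(nchar(ab1$mature), 250)

  j2 <- splice_junctions("chrT", 100, 450, "+")[1, ]
  ab2 <- reconstruct_aberrant_transcript(tm$model, j2, tm$genome)
  expect_equal(unname(ab2$exon_chain),
               matrix(c(0, 450, 100, 500), ncol = 2))
  expect_equal(nchar(ab2$mature), 150)

  ab0 <- reconstruct_aberrant_transcript(tm$model, NULL, tm$genome)
  expect_equal(ab0$mature, extract_transcript_sequence(tm$model,
                                                       tm$genome))
})

test_that("a junction equal to an annotated intron reproduces the mature", {
  tm <- toy_model()
  j <- splice_junctions("chrT", 100, 200, "+")[1, ]
  ab <- reconstruct_aberrant_transcript(tm$model, j, tm$genome)
  expect_true(ab$annotation_equivalent)
  expect_identical(ab$mature,
                   extract_transcript_sequence(tm$model, tm$genome))
})

test_that("reconstruction conserves sequence length", {
  tm <- toy_model()
  j <- splice_junctions("chrT", 100, 250, "+")[1, ]
  ab <- reconstruct_aberrant_transcript(tm$model, j, tm$genome)
  removed <- (200 - 100) + (250 - 200) + (400 - 300)  # intron1 part +
  # ... the aberrant interval splits intron1; removed total is the
  # aberrant intron (150) plus the non-overlapping intron2 (100)
  expect_equal(nchar(ab$mature), 500 - (150 + 100))
  expect_error(reconstruct_aberrant_transcript(
    tm$model, splice_junctions("chrT", 100, 550, "+")[1, ], tm$genome),
    "span")
  expect_error(reconstruct_aberrant_transcript(
    tm$model, splice_junctions("chrT", 100, 250, "-")[1, ], tm$genome),
    "strand")
})

test_that("ORF enumeration follows the every-start, stop-required rule", {
  o1 <- enumerate_orfs("ATGAAATAG", min_aa = 1)
  expect_equal(o1$peptide, "MK")
  expect_equal(c(o1$start, o1$end), c(0L, 9L))

  o2 <- enumerate_orfs("ATGATGAAATAG", min_aa = 1)
  expect_setequal(o2$peptide, c("MMK", "MK"))

  expect_equal(nrow(enumerate_orfs("ATGAAA", min_aa = 1)), 0L)
  expect_error(enumerate_orfs("ATGXXX"), "non-ACGTN")
  # N inside a codon invalidates that ORF
  expect_equal(nrow(enumerate_orfs("ATGANATAG", min_aa = 1)), 0L)
  # length filter
  expect_equal(nrow(enumerate_orfs("ATGAAATAG", min_aa = 3)), 0L)
})

test_that("ORF enumeration matches the substring-scanning oracle", {
  set.seed(12)
  for (i in 1:30) {
    s <- random_seq(sample(60:300, 1))
    mine <- enumerate_orfs(s, min_aa = 1)
    theirs <- oracle_orfs(s, min_aa = 1)
    o <- order(mine$start, mine$end)
    o2 <- order(theirs$start, theirs$end)
    expect_equal(mine[o, ], theirs[o2, ], ignore_attr = TRUE)
  }
  # every reported ORF re-translates cleanly
  s <- random_seq(300)
  orfs <- enumerate_orfs(s, min_aa = 1)
  for (k in seq_len(nrow(orfs))) {
    sub <- substring(s, orfs$start[k] + 1, orfs$end[k])
    expect_equal((orfs$end[k] - orfs$start[k]) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
    expect_equal(aa, paste0(orfs$peptide[k], "*"))
  }
})

test_that("the 50-nt NMD boundary flips exactly between 50 and 51", {
  set.seed(21)
  t50 <- make_ptc_toy(50)
  ab50 <- reconstruct_aberrant_transcript(t50$model, t50$junction,
                                          t50$genome)
  p50 <- predict_ptc(ab50, t50$model)
  expect_false(p50$ptc)
  expect_equal(p50$distance, 50)

  t51 <- make_ptc_toy(51)
  ab51 <- reconstruct_aberrant_transcript(t51$model, t51$junction,
                                          t51$genome)
  p51 <- predict_ptc(ab51, t51$model)
  expect_true(p51$ptc)
  expect_equal(p51$distance, 51)
})

test_that("planted event classes realise their intended PTC fate", {
  co <- memo("small_cohort", simulate_cohort(small_design()))
  canon <- canonical_transcripts(co$annotation)
  tr <- co$truth[startsWith(co$truth$class, "aberrant_up"), ]
  jdf <- co$counts$junctions
  for (i in seq_len(nrow(tr))) {
    j <- jdf[jdf$junction_id == tr$junction_id[i], ]
    ab <- reconstruct_aberrant_transcript(canon[[tr$gene_id[i]]], j,
                                          co$genome)
    p <- predict_ptc(ab, canon[[tr$gene_id[i]]])
    if (tr$event_type[i] == "cryptic_ss") expect_true(p$ptc)
    if (tr$event_type[i] == "utr3") expect_false(p$ptc)
  }
})

test_that("ptc_fraction averages defined calls only", {
  calls <- list(list(ptc = TRUE), list(ptc = TRUE), list(ptc = FALSE),
                list(ptc = NA))
  expect_equal(ptc_fraction(calls), 2 / 3)
  expect_equal(ptc_fraction(c(rep(TRUE, 7), rep(FALSE, 3))), 0.7)
  expect_error(ptc_fraction(list()), "empty")
  expect_error(ptc_fraction(list(list(ptc = NA))), "defined")
})

test_that("tryptic digest cleaves after K/R, not before P", {
  # cleavage after K2 and R9; MK (2 aa) falls below the length floor
  pep <- "MKAAAAAARLLLLLLLK"
  d0 <- tryptic_digest(pep, missed = 0)
  expect_setequal(d0, c("AAAAAAR", "LLLLLLLK"))
  # K before P does not cleave
  expect_equal(tryptic_digest("AAAKPAAAR", missed = 0), "AAAKPAAAR")
  # missed cleavages add concatenations of adjacent segments
  d1 <- tryptic_digest(pep, missed = 1)
  expect_true(all(c("MKAAAAAAR", "AAAAAARLLLLLLLK") %in% d1))
  d2 <- tryptic_digest(pep, missed = 2)
  expect_true("MKAAAAAARLLLLLLLK" %in% d2)
  # the length floor drops 6-mers
  expect_false("MKAAAR" %in% tryptic_digest("MKAAARLLLLLLLK",
                                            missed = 0))
})

test_that("novel peptides are exactly those absent from the reference", {
  ref <- c(refA = "MKAAAAAARLLLLLLLK")
  ab <- list(list(junction_id = "j1",
                  orfs = data.frame(start = 0, end = 3,
                                    peptide = "MKAAAAAARWWWWWWWK")))
  db <- build_peptide_database(ab, ref)
  expect_true("MKAAAAAAR" %in% db$peptides$sequence)
  novel <- db$peptides$sequence[db$peptides$is_novel]
  expect_true("WWWWWWWK" %in% novel)
  expect_false("MKAAAAAAR" %in% novel)
  ref_digest <- unique(unlist(lapply(ref, tryptic_digest)))
  expect_false(any(novel %in% ref_digest))

  # an ORF identical to a reference protein contributes no novel peptide
  ab2 <- list(list(junction_id = "j2",
                   orfs = data.frame(start = 0, end = 3,
                                     peptide = unname(ref))))
  db2 <- build_peptide_database(ab2, ref)
  expect_equal(sum(db2$peptides$is_novel), 0L)

  expect_warning(build_peptide_database(list(), ref), "reference")
  expect_error(build_peptide_database(list(), character(0)), "empty")
})

test_that("a minus-strand twin gene yields identical peptides", {
  tm <- toy_model()
  # twin chromosome: reverse complement; exon (a,b) -> (600-b, 600-a)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tm$genome[["chrT"]])))
  twin <- transcript_model("t2", "g2", "chrR", "-",
                           rbind(c(100, 200), c(300, 400), c(500, 600)))
  gplus <- tm$genome
  gminus <- c(chrR = rc)
  jplus <- splice_junctions("chrT", 100, 250, "+")[1, ]
  jminus <- splice_junctions("chrR", 350, 500, "-")[1, ]
  abp <- reconstruct_aberrant_transcript(tm$model, jplus, gplus)
  abm <- reconstruct_aberrant_transcript(twin, jminus, gminus)
  expect_identical(abp$mature, abm$mature)
  expect_identical(enumerate_orfs(abp$mature, 1),
                   enumerate_orfs(abm$mature, 1))
})
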