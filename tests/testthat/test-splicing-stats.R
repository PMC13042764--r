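make_jcm <- function(chrom, s, e, strand, counts, groups = NULL) {
  jd <- splice_junctions(chrom, s, e, strand)
  colnames(counts) <- colnames(counts) %||%
    paste0("s", seq_len(ncol(counts)))
  meta <- data.frame(sample = colnames(counts),
                     group = groups %||% rep("control", ncol(counts)),
                     tissue = "fc", tdp_status = "none")
  rownames(counts) <- jd$junction_id
  junction_count_matrix(jd, counts, meta)
}

test_that("PSI follows the LSV count-ratio definition", {
  # two junctions sharing a donor, one singleton, one under-covered LSV
  jcm <- make_jcm(
    rep("chr1", 4), c(100, 100, 900, 2000), c(200, 300, 950, 2100),
    rep("+", 4),
    matrix(c(8L, 2L, 12L, 1L,
             1L, 2L, 20L, 2L), ncol = 2))
  psi <- compute_psi(jcm, min_coverage = 5)
  expect_equal(unname(psi$psi[1:2, 1]), c(0.8, 0.2))
  expect_equal(unname(psi$psi[3, 1]), 1.0)       # singleton, covered
  expect_true(is.na(psi$psi[4, 1]))              # 1 read < min_coverage
  expect_true(all(is.na(psi$psi[1:2, 2])))       # LSV total 3 < 5
  expect_equal(unname(psi$psi[3, 2]), 1.0)
  expect_true(is.na(psi$psi[4, 2]))
})

test_that("PSI sums to 1 within quantified LSVs and ignores scaling", {
  co <- memo("small_counts", {
    toy <- generate_toy_genome(small_design())
    simulate_junction_counts(toy)
  })
  psi <- compute_psi(co$counts)
  sums <- rowsum(ifelse(is.na(psi$psi), 0, psi$psi),
                 group = unname(psi$lsv_id), reorder = FALSE)
  quantified <- rowsum((!is.na(psi$psi)) + 0, group = unname(psi$lsv_id),
                       reorder = FALSE) > 0
  expect_true(all(abs(sums[quantified] - 1) < 1e-9))

  jcm3 <- co$counts
  jcm3$counts <- jcm3$counts * 3L
  psi3 <- compute_psi(jcm3)
  keep <- !is.na(psi$psi) & !is.na(psi3$psi)
  expect_equal(psi3$psi[keep], psi$psi[keep])
})

test_that("TNOM matches hand-derived examples", {
  r <- tnom_test(c(0, 0, 0), c(0.5, 0.6, 0.7))
  expect_equal(r$tnom, 0L)
  expect_equal(r$p, 2 / choose(6, 3))   # = 0.1

  r2 <- tnom_test(c(0.1, 0.3), c(0.2, 0.4))
  expect_equal(r2$tnom, 1L)

  r3 <- tnom_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(r3$tnom, 3L)
  expect_equal(r3$p, 1)
})

test_that("TNOM equals the brute-force oracle on small groups", {
  set.seed(1)
  for (na in 2:4) {
    for (nb in 2:4) {
      for (rep in 1:3) {
        a <- round(runif(na), 2)
        b <- round(runif(nb), 2)
        if (rep == 3) a[1] <- b[1]  # force a tie
        r <- tnom_test(a, b)
        expect_equal(r$tnom, oracle_tnom_stat(a, b))
        expect_equal(r$p, oracle_tnom_p(a, b))
      }
    }
  }
})

test_that("the permutation path is seeded and smoothed", {
  a <- c(rnorm(12), 2, 2)
  b <- rnorm(14)
  r1 <- tnom_test(a, b, n_perm = 2000, seed = 5)
  r2 <- tnom_test(a, b, n_perm = 2000, seed = 5)
  expect_identical(r1, r2)
  expect_gte(r1$p, 1 / 2001)  # add-one smoothing floor
})

test_that("heterogen classifies junctions by the three-test rule", {
  meta <- data.frame(sample = paste0("s", 1:24),
                     group = rep(c("ALS", "control"), each = 12),
                     tissue = "fc", tdp_status = "none")
  cases <- meta$sample[1:12]
  ctls <- meta$sample[13:24]
  set.seed(2)
  vals <- rbind(
    # aberrant: control ~0, most cases high
    "chr1:100-200:+" = c(0.3 + rnorm(12, 0, 0.02), rep(0.01, 12)),
    # boundary: control median exactly 0.05 -> normal_up
    "chr1:100-300:+" = c(0.5 + rnorm(12, 0, 0.02),
                         rep(c(0.04, 0.06), 6)),
    # down in cases
    "chr1:500-600:+" = c(rep(0.1, 12) + rnorm(12, 0, 0.01),
                         0.6 + rnorm(12, 0, 0.02)),
    # null
    "chr1:900-990:+" = runif(24, 0.4, 0.6))
  psi <- forge_psi(vals, meta)
  h <- heterogen_test(psi, cases, ctls, seed = 3)
  expect_equal(h$call, c("aberrant_up", "normal_up", "down", "unchanged"))
  expect_true(all(h$p_tnom > 0 & h$p_tnom <= 1))
  # exactly one call per quantified junction, and the up splits partition
  expect_false(any(h$call == "aberrant_up" & h$call == "normal_up"))
})

test_that("median_control exactly at the threshold is normal_up", {
  meta <- data.frame(sample = paste0("s", 1:24),
                     group = rep(c("ALS", "control"), each = 12),
                     tissue = "fc", tdp_status = "none")
  set.seed(4)
  vals <- matrix(c(0.5 + rnorm(12, 0, 0.01), rep(c(0.04, 0.06), 6)),
                 nrow = 1,
                 dimnames = list("chr1:10-100:+", meta$sample))
  h <- heterogen_test(forge_psi(vals, meta), meta$sample[1:12],
                      meta$sample[13:24], seed = 1)
  expect_equal(median(vals[1, 13:24]), 0.05)
  expect_equal(h$call, "normal_up")
})

test_that("groups shrunk below min_samples become unquantified", {
  meta <- data.frame(sample = paste0("s", 1:10),
                     group = rep(c("ALS", "control"), each = 5),
                     tissue = "fc", tdp_status = "none")
  vals <- matrix(c(0.5, 0.4, NA, NA, NA, 0.1, 0.2, 0.1, 0.2, 0.1),
                 nrow = 1,
                 dimnames = list("chr1:10-100:+", meta$sample))
  h <- heterogen_test(forge_psi(vals, meta), meta$sample[1:5],
                      meta$sample[6:10], min_samples = 3, seed = 1)
  expect_equal(h$call, "unquantified")
  expect_error(
    heterogen_test(forge_psi(vals, meta), meta$sample[1:5],
                   meta$sample[4:10]), "disjoint")
})

test_that("two-group comparison flags large, significant pooled shifts", {
  # LSV of two junctions sharing a donor; case 40/100 vs control 10/100
  jcm <- make_jcm(
    rep("chr1", 2), c(100, 100), c(200, 300), rep("+", 2),
    matrix(c(40L, 60L, 10L, 90L), ncol = 2),
    groups = c("ALS", "control"))
  ann <- list(transcript_model("t", "g", "chr1", "+",
                               rbind(c(50, 100), c(300, 400))))
  r <- two_group_delta_psi(jcm, "s1", "s2", ann)
  expect_equal(r$delta_psi[1], 0.30)
  oracle_p <- stats::fisher.test(matrix(c(40, 60, 10, 90), 2))$p.value
  expect_equal(r$p_value[1], oracle_p)
  expect_lt(r$p_value[1], 0.01)
  expect_true(r$significant[1])
  # the second junction is the annotated intron (100,300): not novel
  expect_false(r$is_novel[2])
  expect_true(r$is_novel[1])

  same <- make_jcm(rep("chr1", 2), c(100, 100), c(200, 300),
                   rep("+", 2),
                   matrix(c(30L, 70L, 30L, 70L), ncol = 2),
                   groups = c("ALS", "control"))
  r2 <- two_group_delta_psi(same, "s1", "s2", ann)
  expect_equal(r2$delta_psi[1], 0)
  expect_equal(r2$p_value[1], 1)
  expect_false(r2$significant[1])
})

test_that("positivity rate follows the interpolated 75th percentile", {
  controls <- c(0, 0, 0, 0.02, 0.04, 0.04, 0.05, 0.08)
  expect_equal(unname(quantile(controls, 0.75, type = 7)), 0.0425)
  patients <- c(0.1, 0.2, 0.03, 0.05)
  expect_equal(positivity_rate(patients, controls), 0.75)
  expect_equal(positivity_rate(c(0.01, 0.02), controls), 0)
  expect_error(positivity_rate(numeric(0), controls), "patient")
  expect_error(positivity_rate(0.5, c(0.1, 0.2)), "control")
})

test_that("patients drawn from the control law sit near rate 0.25", {
  set.seed(8)
  rates <- replicate(300, {
    x <- runif(20)
    positivity_rate(x[1:10], x[11:20])
  })
  expect_lt(abs(mean(rates) - 0.25), 0.04)
})

test_that("splice-site dinucleotides respect strand", {
  genome <- c(chrP = paste0("AAAA", "GTCCCCCAG", "TTTT"),
              chrM = paste0("AAAA", "CTCCCCCAC", "TTTT"))
  jp <- splice_junctions("chrP", 4, 13, "+")
  expect_equal(unname(splice_site_dinucleotides(jp[1, ], genome)),
               c("GT", "AG"))
  jm <- splice_junctions("chrM", 4, 13, "-")
  expect_equal(unname(splice_site_dinucleotides(jm[1, ], genome)),
               c("GT", "AG"))
  js <- splice_junctions("chrP", 4, 7, "+")
  expect_error(splice_site_dinucleotides(js[1, ], genome), "shorter")
})
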