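toy_expr <- function() {
  # 4 genes x 40 cells, two types; g1 is a clean Neuron marker, g2 is
  # uniform, g3 detected in exactly 70% of neurons, g4 silent
  set.seed(6)
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:40),
    cell_type = rep(c("Neuron", "Oligodendrocyte"), each = 20),
    sample = rep(c("sA", "sB"), 20), group = "control",
    tissue = "fc", stringsAsFactors = FALSE)
  expr <- rbind(
    g1 = c(rpois(20, 5) + 1L, rep(0L, 20)),
    g2 = rpois(40, 3) + 1L,
    g3 = c(rep(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L), 2),
           rep(0L, 20)),
    g4 = rep(0L, 40))
  colnames(expr) <- cells$cell_id
  list(expr = expr, cells = cells)
}

test_that("profiles normalise per cell and report detection", {
  tx <- toy_expr()
  pr <- summarize_cell_types(tx$expr, tx$cells, group = "control")
  expect_equal(unname(pr$pct_detected["g1", ]), c(1, 0))
  expect_equal(unname(pr$pct_detected["g3", "Neuron"]), 0.7)
  # doubling a cell's raw counts leaves its normalised vector unchanged
  e2 <- tx$expr
  e2[, 1] <- e2[, 1] * 2L
  pr2 <- summarize_cell_types(e2, tx$cells, group = "control")
  expect_equal(pr2$norm[, 1], pr$norm[, 1])
  expect_error(summarize_cell_types(tx$expr[, 0], tx$cells[0, ]),
               "empty")
})

test_that("strict marker calls enforce all three thresholds strictly", {
  tx <- toy_expr()
  pr <- summarize_cell_types(tx$expr, tx$cells, group = "control")
  mk <- call_markers(pr, mode = "strict")
  g1n <- mk[mk$gene == "g1" & mk$cell_type == "Neuron", ]
  expect_true(g1n$strict)
  expect_false(any(mk$strict[mk$gene == "g1" &
                               mk$cell_type != "Neuron"]))
  # pct1 exactly 0.7 fails the strict > rule
  g3n <- mk[mk$gene == "g3" & mk$cell_type == "Neuron", ]
  expect_equal(g3n$pct1, 0.7)
  expect_false(g3n$strict)
  # uniformly expressed gene never strict
  expect_false(any(mk$strict[mk$gene == "g2"]))
})

test_that("strict markers are a subset of enriched markers", {
  pr <- shared_profile()
  st <- shared_markers()
  en <- call_markers(pr, mode = "enriched")
  key <- function(df, flag) paste(df$gene, df$cell_type)[df[[flag]]]
  expect_true(all(key(st, "strict") %in% key(en, "enriched")))
})

test_that("planted strict markers are recovered exactly", {
  co <- shared_cohort()
  mk <- shared_markers()
  found <- mk[mk$strict, c("gene", "cell_type")]
  planted <- co$markers
  expect_setequal(paste(found$gene, found$cell_type),
                  paste(planted$gene_id, planted$cell_type))
})

test_that("neuron-to-oligo score is a log ratio with antisymmetry", {
  pr <- structure(list(mean_expr = matrix(
    c(4, 1, 2, 2), nrow = 2, byrow = TRUE,
    dimnames = list(c("gA", "gB"), c("Neuron", "Oligodendrocyte")))),
    class = "celltype_profile")
  expect_equal(neuron_to_oligo_score(pr, "gA"), log2(4.01 / 1.01),
               tolerance = 1e-12)
  expect_equal(round(neuron_to_oligo_score(pr, "gA"), 3), 1.989)
  expect_equal(neuron_to_oligo_score(pr, "gB"), 0)
  expect_equal(
    neuron_to_oligo_score(pr, "gA"),
    -neuron_to_oligo_score(pr, "gA", neuron_types = "Oligodendrocyte",
                           oligo_type = "Neuron"))
  expect_error(neuron_to_oligo_score(pr, "missing"), "absent")
})

test_that("fisher enrichment builds the table and odds ratio as stated", {
  u <- paste0("g", 1:6)
  r <- fisher_enrichment(c("g1", "g2", "g3"), c("g1", "g2", "g4"), u)
  expect_equal(unname(r$table), c(2, 1, 1, 2))
  expect_equal(r$odds_ratio, 4.0)

  u2 <- paste0("g", 1:20)
  r2 <- fisher_enrichment(u2[1:10], u2[1:10], u2)
  expect_equal(unname(r2$table), c(10, 0, 0, 10))
  expect_equal(r2$odds_ratio, 441.0)  # Haldane +0.5 on every cell

  expect_error(fisher_enrichment("gX", "g1", u), "subsets")
  expect_error(fisher_enrichment("g1", "g1", character(0)), "universe")
})

test_that("enrichment p matches fisher.test on random tables", {
  set.seed(9)
  for (i in 1:60) {
    n <- sample(8:40, 1)
    u <- paste0("g", seq_len(n))
    q <- sample(u, sample(1:n, 1))
    a <- sample(u, sample(1:n, 1))
    r <- fisher_enrichment(q, a, u)
    ft <- stats::fisher.test(matrix(r$table[c("a", "c", "b", "d")], 2))
    expect_equal(r$p_value, ft$p.value, tolerance = 1e-9)
  }
})

test_that("splicing genes are most enriched in their planted cell type", {
  co <- shared_cohort()
  universe <- vapply(co$annotation, function(m) m$gene_id, "")
  mk <- shared_markers()
  st <- mk[mk$strict, ]
  als_genes <- unique(co$truth$gene_id[co$truth$class == "aberrant_up_ALS"])
  ors <- vapply(unique(st$cell_type), function(ct)
    fisher_enrichment(als_genes, st$gene[st$cell_type == ct],
                      universe)$odds_ratio, 0)
  expect_equal(names(which.max(ors)), "Oligodendrocyte")
  expect_gt(max(ors) / max(ors[names(ors) != "Oligodendrocyte"]), 1)
})

test_that("composition summaries use per-sample proportions", {
  cells <- data.frame(
    cell_id = sprintf("c%03d", 1:100),
    cell_type = rep(c("Neuron", "Glia"), c(30, 70)),
    sample = "s1", group = "ALS", stringsAsFactors = FALSE)
  cs <- composition_summary(cells)
  expect_equal(sort(cs$per_sample$proportion), c(0.3, 0.7))
  expect_equal(cs$per_group$median[cs$per_group$cell_type == "Glia"],
               0.7)
  expect_error(composition_summary(cells[0, ]), "no cells")
})

test_that("low-fraction subgroup selection floors and breaks ties", {
  p <- setNames(c(0.5, 0.1, 0.3, 0.2, 0.4, 0.15, 0.35, 0.25, 0.45, 0.05),
                paste0("s", 1:10))
  sel <- select_low_fraction_subgroup(p, 0.6)
  expect_length(sel, 6)
  expect_setequal(sel, c("s10", "s2", "s6", "s4", "s8", "s3"))
  expect_setequal(select_low_fraction_subgroup(p, 1.0), names(p))
  # tied boundary: lexicographically smaller id wins
  pt <- setNames(c(0.1, 0.2, 0.2, 0.9), c("sd", "sb", "sa", "sc"))
  expect_setequal(select_low_fraction_subgroup(pt, 0.5), c("sd", "sa"))
  expect_error(select_low_fraction_subgroup(numeric(0), 0.5), "empty")
  expect_error(select_low_fraction_subgroup(p, 0), "fraction")
})
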