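# hand-built heterogen calls and markers exercising the nomination rules
toy_calls <- function() {
  data.frame(
    junction_id = c("j1", "j1", "j2", "j2", "j3", "j4", "j5"),
    call = c("aberrant_up", "unchanged",       # j1: ALS in one tissue
             "aberrant_up", "aberrant_up",     # j2: ALS and FTD
             "aberrant_up",                    # j3: non-marker gene
             "aberrant_up",                    # j4: cerebellum only
             "aberrant_up"),                   # j5: FTD, neuron marker
    disease = c("ALS", "ALS", "ALS", "FTD", "ALS", "ALS", "FTD"),
    tissue = c("frontal_cortex", "temporal_cortex",
               "frontal_cortex", "frontal_cortex",
               "frontal_cortex", "cerebellum", "frontal_cortex"),
    stringsAsFactors = FALSE)
}

toy_markers <- function() {
  data.frame(gene = c("gOli", "gNeu"),
             cell_type = c("Oligodendrocyte", "Neuron"),
             log2fc = 5, pct1 = 0.9, pct2 = 0.01, p_value = 1e-6,
             strict = TRUE, stringsAsFactors = FALSE)
}

test_that("nomination enforces marker, tissue and disease specificity", {
  jg <- c(j1 = "gOli", j2 = "gOli", j3 = "gOther", j4 = "gOli",
          j5 = "gNeu")
  bio <- nominate_biomarkers(toy_calls(), toy_markers(), jg)
  expect_setequal(bio$junction_id, c("j1", "j5"))
  expect_equal(bio$disease[bio$junction_id == "j1"], "ALS")
  expect_equal(bio$cell_type[bio$junction_id == "j1"],
               "Oligodendrocyte")
  expect_equal(bio$disease[bio$junction_id == "j5"], "FTD")
  # j2 fails disease specificity, j3 the marker rule, j4 the tissue rule
  expect_false("j2" %in% bio$junction_id)
  expect_false("j3" %in% bio$junction_id)
  expect_false("j4" %in% bio$junction_id)
})

test_that("junctions mapping to no gene are skipped with a warning", {
  jg <- c(j1 = "gOli", j2 = "gOli", j3 = "gOther", j4 = "gOli",
          j5 = "")
  expect_warning(bio <- nominate_biomarkers(toy_calls(), toy_markers(),
                                            jg), "no gene")
  expect_equal(bio$junction_id, "j1")
})

test_that("requiring two supporting tissues tightens nomination", {
  calls <- toy_calls()
  calls$call[2] <- "aberrant_up"  # j1 now supported in both cortices
  jg <- c(j1 = "gOli", j2 = "gOli", j3 = "gOther", j4 = "gOli",
          j5 = "gNeu")
  bio <- nominate_biomarkers(calls, toy_markers(), jg, min_tissues = 2)
  expect_equal(bio$junction_id, "j1")
  expect_equal(bio$supporting_tissues,
               "frontal_cortex;temporal_cortex")
})

test_that("train/test splits are stratified, seeded and validated", {
  samples <- paste0("s", 1:40)
  labels <- rep(c("ALS", "FTD"), each = 20)
  sp <- split_train_test(samples, labels, 0.3, seed = 5)
  expect_length(sp$test, 12)
  expect_length(sp$train, 28)
  expect_equal(sum(sp$test %in% samples[1:20]), 6)
  sp2 <- split_train_test(samples, labels, 0.3, seed = 5)
  expect_identical(sp, sp2)
  expect_error(split_train_test(samples, labels, 0, seed = 1),
               "test_fraction")
  expect_error(split_train_test("s1", "ALS", 0.3, seed = 1), ">= 2")
})

test_that("fold assignment is stratified and validated", {
  labels <- setNames(rep(c("ALS", "FTD"), each = 10), paste0("s", 1:20))
  f <- make_folds(labels, 5, seed = 2)
  expect_equal(as.integer(table(f)), rep(4L, 5))
  for (k in 1:5)
    expect_equal(sum(labels[f == k] == "ALS"), 2)
  expect_error(make_folds(labels, 1, seed = 1), "k must be")
  expect_error(make_folds(labels, 11, seed = 1), "smallest class")
})

test_that("the held-out classifier separates the planted diseases", {
  rep_rf <- memo("rf_report", {
    psi <- shared_psi()
    meta <- psi$metadata
    patients <- meta$sample[meta$group %in% c("ALS", "FTD")]
    labels <- setNames(meta$group[match(patients, meta$sample)],
                       patients)
    split <- split_train_test(patients, labels, 0.3, seed = 42)
    train_and_evaluate(psi, labels, split, shared_markers(),
                       setNames(shared_cohort()$counts$junctions$gene_id,
                                shared_cohort()$counts$junctions$junction_id),
                       seed = 42)
  })
  expect_gte(rep_rf$auc, 0.95)
  expect_true(all(abs(rowSums(rep_rf$confidences) - 1) < 1e-9))
  # biomarker pairing invariant
  expect_true(all(
    rep_rf$biomarkers$cell_type[rep_rf$biomarkers$disease == "ALS"] ==
      "Oligodendrocyte"))
  expect_true(all(
    rep_rf$biomarkers$cell_type[rep_rf$biomarkers$disease == "FTD"] ==
      "Neuron"))
})

test_that("feature selection ignores held-out samples entirely", {
  psi <- shared_psi()
  meta <- psi$metadata
  patients <- meta$sample[meta$group %in% c("ALS", "FTD")]
  labels <- setNames(meta$group[match(patients, meta$sample)], patients)
  split <- split_train_test(patients, labels, 0.3, seed = 42)
  rep_rf <- memo("rf_report", stop("fixture must exist"))

  # drop the test samples from the matrix altogether and re-nominate
  keep <- meta$sample[!(meta$sample %in% split$test)]
  psi_cut <- psi
  psi_cut$psi <- psi$psi[, keep]
  psi_cut$metadata <- meta[meta$sample %in% keep, ]
  jg <- setNames(shared_cohort()$counts$junctions$gene_id,
                 shared_cohort()$counts$junctions$junction_id)
  bio_cut <- splicemark:::nominate_on_samples(
    psi_cut, split$train, shared_markers(), jg,
    c(ALS = "Oligodendrocyte", FTD = "Neuron"), "cerebellum",
    3, 0.05, 0.05, 10000, 42)
  expect_identical(sort(unique(bio_cut$junction_id)),
                   sort(rep_rf$features))
})

test_that("external scoring applies the confidence threshold", {
  rep_rf <- memo("rf_report", stop("fixture must exist"))
  psi <- shared_psi()
  sc <- score_external(rep_rf, psi, samples = rep_rf$model$test %||%
                         colnames(psi$psi)[1:4], threshold = 1.0)
  expect_true(all(sc$label == "unclassified"))
})
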