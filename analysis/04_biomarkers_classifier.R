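#!/usr/bin/env Rscript
# Stage 4 — biomarker nomination and the leakage-safe random forest.
#
# Nominates disease- and cell-type-specific aberrant junctions (strict
# marker gene + aberrant_up in >= 1 eligible tissue + absent from the
# other disease), attaches positivity rates, then evaluates a random
# forest with in-split feature selection: 70/30 held-out split, 5-fold
# CV, a permuted-label null, and external scoring of fresh synthetic
# cohorts at confidence 0.8.

suppressPackageStartupMessages(library(splicemark))
seed <- 42

jcm <- read_junction_counts("results/cohort/junction_counts.tsv",
                            "results/cohort/sample_metadata.tsv")
psi <- compute_psi(jcm, min_coverage = 10)
het <- read.delim("results/heterogen_results.tsv")
markers <- read.delim("results/markers.tsv")
annotation <- read_gene_annotation("results/cohort/annotation.gtf")
jg <- assign_junction_genes(jcm$junctions, annotation)

bio <- nominate_biomarkers(het, markers, jg, psi = psi)
write.table(bio, "results/biomarkers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("biomarkers: ", sum(bio$disease == "ALS"),
        " ALS/oligodendrocyte, ", sum(bio$disease == "FTD"),
        " FTD/neuron")
top <- bio[order(-bio$positivity_rate), ][1, ]
message(sprintf("highest positivity rate: %s (%s, %.2f)",
                top$junction_id, top$disease, top$positivity_rate))

meta <- psi$metadata
patients <- meta$sample[meta$group %in% c("ALS", "FTD")]
labels <- setNames(meta$group[match(patients, meta$sample)], patients)
split <- split_train_test(patients, labels, 0.3, seed = seed)
fit <- train_and_evaluate(psi, labels, split, markers, jg, seed = seed)
write.table(fit$roc, "results/roc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("held-out AUC: %.3f (%d features)", fit$auc,
                length(fit$features)))

cv <- cross_validate(psi, labels, k = 5, markers, jg, seed = seed)
message(sprintf("5-fold CV AUC per fold: %s; mean %.3f",
                paste(sprintf("%.2f", cv$fold_auc), collapse = " "),
                cv$mean_auc))

null_auc <- evaluate_permuted_labels(fit, psi, labels, split, seed = 99)
message(sprintf("permuted-label null AUC: %.3f (chance reference)",
                null_auc))

# external cohorts simulated from the same planted truth
toy <- generate_toy_genome(cohort_design(seed = seed))
ext_meta <- data.frame(
  sample = c(sprintf("ext.ALS.%02d", 1:20),
             sprintf("ext.control.%02d", 1:20)),
  group = rep(c("ALS", "control"), each = 20),
  tissue = "frontal_cortex", tdp_status = "TDP")
ext <- simulate_junction_counts(toy, samples = ext_meta, seed = 4242)
sc <- score_external(fit, compute_psi(ext$counts),
                     samples = ext_meta$sample, threshold = 0.8)
write.table(sc, "results/predictions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf(
  "external scoring: %.0f%% of disease samples labelled ALS; %.0f%% of controls unclassified",
  100 * mean(sc$label[ext_meta$group == "ALS"] == "ALS"),
  100 * mean(sc$label[ext_meta$group == "control"] == "unclassified")))
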