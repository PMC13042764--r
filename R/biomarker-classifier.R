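# Nominates disease- and cell-type-specific aberrant splicing junction
# biomarkers and evaluates them with a leakage-safe random-forest
# classifier: feature (biomarker) selection is re-run inside every
# training split / fold, never on held-out samples.

#' Nominate disease- and cell-type-specific biomarker junctions
#'
#' A junction is a biomarker for disease D iff (i) its gene is a strict
#' marker of D's designated cell type, (ii) it is called `aberrant_up` for
#' D in at least `min_tissues` eligible tissues (tissues in
#' `excluded_tissues` are not eligible), and (iii) it is not `aberrant_up`
#' for any other disease in any tissue. The positivity rate (fraction of
#' that disease's patients above the 75th percentile of control PSI,
#' pooled over supporting tissues) is attached when a PSI matrix is
#' supplied.
#'
#' @param het_calls data.frame of heterogen results rows with added
#'   `disease` and `tissue` columns (rbind over per-disease-per-tissue
#'   runs of [heterogen_test()])
#' @param markers marker calls from [call_markers()] (strict mode)
#' @param junction_genes named character vector junction_id -> gene_id
#' @param disease_celltype named map disease -> cell type
#' @param excluded_tissues tissues ineligible for support (default
#'   `"cerebellum"`)
#' @param min_tissues minimum supporting tissues (default 1)
#' @param psi optional `psi_matrix` for positivity rates
#' @return data.frame: `junction_id`, `gene`, `disease`, `cell_type`,
#'   `supporting_tissues` (`;`-separated), `positivity_rate`
#' @export
nominate_biomarkers <- function(het_calls, markers, junction_genes,
                                disease_celltype = c(
                                  ALS = "Oligodendrocyte",
                                  FTD = "Neuron"),
                                excluded_tissues = "cerebellum",
                                min_tissues = 1, psi = NULL) {
  stopifnot(all(c("disease", "tissue", "junction_id", "call") %in%
                  colnames(het_calls)))
  strict_genes <- split(markers$gene[markers$strict],
                        markers$cell_type[markers$strict])
  ab <- het_calls[het_calls$call == "aberrant_up", , drop = FALSE]
  eligible <- ab[!(ab$tissue %in% excluded_tissues), , drop = FALSE]
  out <- list()
  for (dis in names(disease_celltype)) {
    ct <- disease_celltype[[dis]]
    sup <- eligible[eligible$disease == dis, , drop = FALSE]
    if (nrow(sup) == 0) next
    tissues_of <- split(sup$tissue, sup$junction_id)
    for (jid in names(tissues_of)) {
      if (length(unique(tissues_of[[jid]])) < min_tissues) next
      gene <- unname(junction_genes[jid])
      if (is.null(gene) || is.na(gene) || !nzchar(gene)) {
        warning("junction ", jid, " maps to no gene; skipped")
        next
      }
      if (!gene %in% (strict_genes[[ct]] %||% character(0))) next
      other <- ab$junction_id[ab$disease != dis]
      if (jid %in% other) next
      out[[length(out) + 1]] <- data.frame(
        junction_id = jid, gene = gene, disease = dis, cell_type = ct,
        supporting_tissues = paste(sort(unique(tissues_of[[jid]])),
                                   collapse = ";"),
        positivity_rate = NA_real_, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    junction_id = character(0), gene = character(0),
    disease = character(0), cell_type = character(0),
    supporting_tissues = character(0), positivity_rate = numeric(0),
    stringsAsFactors = FALSE)
  if (!is.null(psi) && nrow(res) > 0) {
    meta <- psi$metadata
    for (i in seq_len(nrow(res))) {
      tiss <- strsplit(res$supporting_tissues[i], ";")[[1]]
      pat <- meta$sample[meta$group == res$disease[i] &
                           meta$tissue %in% tiss]
      ctl <- meta$sample[meta$group == "control" & meta$tissue %in% tiss]
      if (res$junction_id[i] %in% rownames(psi$psi) &&
          length(ctl) >= 4 && length(pat) > 0) {
        res$positivity_rate[i] <- tryCatch(
          positivity_rate(psi$psi[res$junction_id[i], pat],
                          psi$psi[res$junction_id[i], ctl]),
          error = function(e) NA_real_)
      }
    }
  }
  rownames(res) <- NULL
  res
}

#' Stratified train/test split
#'
#' @param samples character vector of sample ids
#' @param labels class labels, parallel to `samples`
#' @param test_fraction fraction held out (in (0, 1))
#' @param seed integer seed; identical seeds give identical splits
#' @return list with `train` and `test` sample id vectors
#' @export
split_train_test <- function(samples, labels, test_fraction, seed) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs >= 2 samples")
  set.seed(seed)
  test <- character(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    k <- max(1L, round(test_fraction * length(idx)))
    test <- c(test, samples[sample(idx, k)])
  }
  list(train = setdiff(samples, test), test = test)
}

#' Stratified fold assignment for k-fold CV
#'
#' @param labels class labels
#' @param k folds; must not exceed the smallest class size, and k >= 2
#' @param seed integer seed
#' @return integer fold id per sample
#' @export
make_folds <- function(labels, k, seed) {
  if (k < 2) stop("k must be >= 2")
  tab <- table(labels)
  if (k > min(tab)) stop("k exceeds the smallest class size")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# per-sample feature matrix: PSI of the nominated junctions, missing -> 0
psi_feature_matrix <- function(psi, junction_ids, samples) {
  X <- matrix(0, length(samples), length(junction_ids),
              dimnames = list(samples, junction_ids))
  present <- intersect(junction_ids, rownames(psi$psi))
  if (length(present) > 0) {
    vals <- t(psi$psi[present, samples, drop = FALSE])
    vals[is.na(vals)] <- 0
    X[, present] <- vals
  }
  colnames(X) <- make.names(colnames(X), unique = TRUE)  # forest-safe names
  X
}

# in-split biomarker nomination: heterogen per disease x tissue using only
# the given patient samples (all controls remain available), then the
# nomination rule
nominate_on_samples <- function(psi, patient_samples, markers,
                                junction_genes, disease_celltype,
                                excluded_tissues, min_samples, alpha,
                                aberrant_control_median, n_perm, seed) {
  meta <- psi$metadata
  calls <- list()
  for (dis in names(disease_celltype)) {
    for (tis in unique(meta$tissue)) {
      cases <- intersect(patient_samples,
                         meta$sample[meta$group == dis &
                                       meta$tissue == tis])
      ctls <- meta$sample[meta$group == "control" & meta$tissue == tis]
      if (length(cases) < min_samples || length(ctls) < min_samples) next
      h <- heterogen_test(psi, cases, ctls, min_samples = min_samples,
                          alpha = alpha,
                          aberrant_control_median = aberrant_control_median,
                          n_perm = n_perm, seed = seed)
      h$disease <- dis
      h$tissue <- tis
      calls[[length(calls) + 1]] <- h
    }
  }
  if (length(calls) == 0) return(NULL)
  nominate_biomarkers(do.call(rbind, calls), markers, junction_genes,
                      disease_celltype, excluded_tissues)
}

#' Train and evaluate the biomarker random forest
#'
#' Re-runs biomarker nomination on the training split only (leakage-safe),
#' builds per-sample PSI features of the nominated junctions (missing PSI
#' encoded as 0), trains a seeded random forest, and evaluates ROC/AUC on
#' the held-out test split. Per-sample class confidence is the fraction of
#' ensemble votes.
#'
#' @param psi a `psi_matrix` covering all samples
#' @param labels named character vector sample -> class (e.g. disease)
#' @param split list with `train`/`test` from [split_train_test()]
#' @param markers strict marker calls
#' @param junction_genes named junction_id -> gene_id map
#' @param disease_celltype disease -> cell type map
#' @param ntree ensemble size (default 500)
#' @param seed integer seed
#' @param excluded_tissues,min_samples,alpha,aberrant_control_median,n_perm
#'   nomination settings, passed through to [heterogen_test()]
#' @return object of class `classifier_report`: list with `auc`, `roc`
#'   (data.frame), `confidences` (per test sample, both classes; rows sum
#'   to 1), `features`, `biomarkers`, `model`, `classes`, `seed`
#' @export
train_and_evaluate <- function(psi, labels, split, markers,
                               junction_genes,
                               disease_celltype = c(
                                 ALS = "Oligodendrocyte", FTD = "Neuron"),
                               ntree = 500, seed = 1,
                               excluded_tissues = "cerebellum",
                               min_samples = 3, alpha = 0.05,
                               aberrant_control_median = 0.05,
                               n_perm = 10000) {
  bio <- nominate_on_samples(psi, split$train, markers, junction_genes,
                             disease_celltype, excluded_tissues,
                             min_samples, alpha, aberrant_control_median,
                             n_perm, seed)
  if (is.null(bio) || nrow(bio) == 0)
    stop("no biomarker features nominated in the training split; ",
         "check sample sizes and marker calls")
  feats <- unique(bio$junction_id)
  Xtr <- psi_feature_matrix(psi, feats, split$train)
  Xte <- psi_feature_matrix(psi, feats, split$test)
  ytr <- factor(labels[split$train])
  yte <- factor(labels[split$test], levels = levels(ytr))
  set.seed(seed)
  rf <- randomForest::randomForest(Xtr, ytr, ntree = ntree)
  prob <- predict(rf, Xte, type = "prob")
  pos <- levels(ytr)[1]
  roc_obj <- pROC::roc(response = yte, predictor = prob[, pos],
                       levels = rev(levels(ytr)), direction = "<",
                       quiet = TRUE)
  structure(list(
    auc = as.numeric(pROC::auc(roc_obj)),
    roc = data.frame(threshold = roc_obj$thresholds,
                     sensitivity = roc_obj$sensitivities,
                     specificity = roc_obj$specificities),
    confidences = as.data.frame(prob),
    features = feats, biomarkers = bio, model = rf,
    classes = levels(ytr), seed = seed), class = "classifier_report")
}

#' k-fold cross-validation with in-fold feature selection
#'
#' Stratified k folds over the labelled samples; biomarker nomination is
#' repeated within each fold's training portion before training, so no
#' held-out sample influences feature choice.
#'
#' @inheritParams train_and_evaluate
#' @param k folds (default 5)
#' @return object of class `classifier_report` with `fold_auc`,
#'   `mean_auc`, pooled `roc`, `confidences` for every sample (predicted
#'   out of fold), `features` per fold, `folds`, `seed`
#' @export
cross_validate <- function(psi, labels, k = 5, markers, junction_genes,
                           disease_celltype = c(ALS = "Oligodendrocyte",
                                                FTD = "Neuron"),
                           ntree = 500, seed = 1,
                           excluded_tissues = "cerebellum",
                           min_samples = 3, alpha = 0.05,
                           aberrant_control_median = 0.05,
                           n_perm = 10000) {
  samples <- names(labels)
  fold <- make_folds(labels, k, seed)
  lv <- levels(factor(labels))
  pos <- lv[1]
  fold_auc <- numeric(k)
  feats_per_fold <- vector("list", k)
  conf <- matrix(NA_real_, length(samples), length(lv),
                 dimnames = list(samples, lv))
  for (f in seq_len(k)) {
    train <- samples[fold != f]
    test <- samples[fold == f]
    bio <- nominate_on_samples(psi, train, markers, junction_genes,
                               disease_celltype, excluded_tissues,
                               min_samples, alpha,
                               aberrant_control_median, n_perm,
                               derive_seed(seed, f))
    if (is.null(bio) || nrow(bio) == 0)
      stop("no biomarker features nominated in fold ", f)
    feats <- unique(bio$junction_id)
    feats_per_fold[[f]] <- feats
    Xtr <- psi_feature_matrix(psi, feats, train)
    Xte <- psi_feature_matrix(psi, feats, test)
    ytr <- factor(labels[train], levels = lv)
    set.seed(derive_seed(seed, 100 + f))
    rf <- randomForest::randomForest(Xtr, ytr, ntree = ntree)
    prob <- predict(rf, Xte, type = "prob")
    conf[test, ] <- prob[, lv]
    yte <- factor(labels[test], levels = lv)
    roc_f <- pROC::roc(response = yte, predictor = prob[, pos],
                       levels = rev(lv), direction = "<", quiet = TRUE)
    fold_auc[f] <- as.numeric(pROC::auc(roc_f))
  }
  roc_all <- pROC::roc(response = factor(labels, levels = lv),
                       predictor = conf[, pos], levels = rev(lv),
                       direction = "<", quiet = TRUE)
  structure(list(
    fold_auc = fold_auc, mean_auc = mean(fold_auc),
    auc = as.numeric(pROC::auc(roc_all)),
    roc = data.frame(threshold = roc_all$thresholds,
                     sensitivity = roc_all$sensitivities,
                     specificity = roc_all$specificities),
    confidences = as.data.frame(conf),
    features = feats_per_fold, folds = fold, classes = lv, seed = seed),
    class = "classifier_report")
}

#' Permutation null of the trained classifier
#'
#' Retrains the ensemble on the report's feature set with class labels
#' permuted and returns the mean held-out AUC over `n_perm` seeded
#' permutations — a chance-level reference for the real model. The
#' feature set is kept fixed because under permuted labels the nomination
#' step typically selects no features at all, leaving no model to
#' evaluate; averaging over permutations tames the variance of a single
#' small held-out split.
#'
#' @param report a `classifier_report` from [train_and_evaluate()]
#' @param psi the `psi_matrix` used for training
#' @param labels named sample -> class vector
#' @param split the train/test split used
#' @param seed permutation seed
#' @param n_perm number of label permutations averaged (default 20)
#' @return mean AUC on the held-out split under permuted labels
#' @export
evaluate_permuted_labels <- function(report, psi, labels, split, seed,
                                     n_perm = 20) {
  Xtr <- psi_feature_matrix(psi, report$features, split$train)
  Xte <- psi_feature_matrix(psi, report$features, split$test)
  pos <- report$classes[1]
  aucs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(derive_seed(seed, b))
    perm <- setNames(sample(unname(labels)), names(labels))
    ytr <- factor(perm[split$train], levels = report$classes)
    yte <- factor(perm[split$test], levels = report$classes)
    if (length(unique(yte)) < 2) {
      aucs[b] <- 0.5
      next
    }
    set.seed(derive_seed(seed, 1000 + b))
    rf <- randomForest::randomForest(Xtr, ytr,
                                     ntree = report$model$ntree)
    prob <- predict(rf, Xte, type = "prob")
    roc <- pROC::roc(response = yte, predictor = prob[, pos],
                     levels = rev(report$classes), direction = "<",
                     quiet = TRUE)
    aucs[b] <- as.numeric(pROC::auc(roc))
  }
  mean(aucs)
}

#' Score external samples with a trained model
#'
#' Predicts class confidences for new samples; a label is assigned only
#' when the top confidence strictly exceeds `threshold`, otherwise the
#' sample is `"unclassified"`. Feature junctions absent from the external
#' matrix are filled with 0 and counted in a coverage warning.
#'
#' @param report a `classifier_report` from [train_and_evaluate()]
#' @param psi_external a `psi_matrix` for the external samples
#' @param samples sample ids to score (default: all columns)
#' @param threshold confidence threshold (default 0.8)
#' @return data.frame: `sample`, one confidence column per class, `label`
#' @export
score_external <- function(report, psi_external, samples = NULL,
                           threshold = 0.8) {
  samples <- samples %||% colnames(psi_external$psi)
  missing <- setdiff(report$features, rownames(psi_external$psi))
  if (length(missing) > 0)
    warning(length(missing), " of ", length(report$features),
            " feature junction(s) absent from the external matrix; ",
            "filled with 0")
  X <- psi_feature_matrix(psi_external, report$features, samples)
  prob <- predict(report$model, X, type = "prob")
  top <- apply(prob, 1, max)
  lab <- colnames(prob)[apply(prob, 1, which.max)]
  lab[top <= threshold] <- "unclassified"
  out <- data.frame(sample = samples, as.data.frame(prob),
                    label = lab, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
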