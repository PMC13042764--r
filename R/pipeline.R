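# Config-driven orchestration of the full analysis: simulate -> PSI ->
# heterogen -> markers -> nomination -> classification -> transcript
# effects -> peptide database -> RBP context -> report, with a manifest
# (file hashes, config hash, seed) for provenance.

#' Default run configuration
#'
#' All thresholds the analysis uses, at their reference values: control
#' median 0.05 for the aberrant call, three-test alpha 0.05, strict marker
#' thresholds (log2FC > 1, pct1 > 0.7, pct2 < 0.1), +/-150 nt RBP flank,
#' 0.75 positivity quantile, 0.8 confidence threshold, 0.3 test fraction,
#' 5 CV folds, 50-nt NMD boundary, tryptic digest with <= 2 missed
#' cleavages and 7-40 aa peptides.
#'
#' @param seed integer seed (mandatory; drives every stochastic step)
#' @param output_dir directory for stage outputs
#' @return named list of class `run_config`
#' @export
default_run_config <- function(seed, output_dir = tempfile("splicemark_")) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(
    seed = seed,
    output_dir = output_dir,
    min_coverage = 10,
    alpha = 0.05,
    aberrant_control_median = 0.05,
    n_perm = 10000,
    min_samples = 3,
    twogroup_alpha = 0.01,
    twogroup_delta = 0.1,
    marker_log2fc = 1, marker_pct1 = 0.7, marker_pct2 = 0.1,
    flank_nt = 150,
    positivity_quantile = 0.75,
    confidence_threshold = 0.8,
    test_fraction = 0.3,
    k_folds = 5,
    ntree = 500,
    nmd_nt = 50,
    digest_missed = 2, digest_len = c(7, 40), min_orf_aa = 7,
    excluded_tissues = "cerebellum",
    disease_celltype = c(ALS = "Oligodendrocyte", FTD = "Neuron")),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values in the file override the defaults; unknown keys error.
#'
#' @param path YAML file
#' @param seed fallback seed when the file does not set one
#' @return a `run_config`
#' @export
read_run_config <- function(path, seed = NULL) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$seed) && is.null(seed))
    stop("config must set a seed")
  cfg <- default_run_config(seed = vals$seed %||% seed)
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#' @param config a `run_config`
#' @return `config`, invisibly; errors before any stage runs
#' @export
validate_run_config <- function(config) {
  c0 <- config
  in01 <- c(alpha = c0$alpha, twogroup_alpha = c0$twogroup_alpha,
            aberrant_control_median = c0$aberrant_control_median,
            positivity_quantile = c0$positivity_quantile,
            confidence_threshold = c0$confidence_threshold,
            marker_pct1 = c0$marker_pct1, marker_pct2 = c0$marker_pct2)
  bad <- names(in01)[in01 <= 0 | in01 > 1]
  if (length(bad) > 0)
    stop("config value(s) outside (0, 1]: ", paste(bad, collapse = ", "))
  if (c0$test_fraction <= 0 || c0$test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  stopifnot(c0$min_coverage >= 1, c0$k_folds >= 2, c0$flank_nt >= 1,
            c0$nmd_nt >= 0, c0$ntree >= 1, c0$min_samples >= 2,
            c0$min_orf_aa >= 1, c0$digest_missed >= 0,
            length(c0$digest_len) == 2)
  if (is.null(c0$seed)) stop("seed is mandatory")
  invisible(config)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage in dependency order, writes each stage's tables
#' under `config$output_dir`, and returns a report of per-stage counts
#' plus a manifest of output hashes. Outputs are a pure function of
#' (design, config); reruns with the same seed are byte-identical.
#'
#' @param config a `run_config`
#' @param design optional [cohort_design()] (default: the reference design
#'   under `config$seed`)
#' @return list of class `run_report`: stage summaries, key result tables
#'   and `manifest`
#' @export
run_pipeline <- function(config, design = NULL) {
  validate_run_config(config)
  design <- design %||% cohort_design(seed = config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  cohort <- simulate_cohort(design)
  write_cohort(cohort, out("inputs"))

  psi <- compute_psi(cohort$counts, min_coverage = config$min_coverage)
  write_psi_matrix(psi, out("psi_matrix.tsv"))

  meta <- psi$metadata
  het <- list()
  for (dis in names(config$disease_celltype)) {
    for (tis in unique(meta$tissue)) {
      cases <- meta$sample[meta$group == dis & meta$tissue == tis]
      ctls <- meta$sample[meta$group == "control" & meta$tissue == tis]
      if (length(cases) == 0 || length(ctls) == 0) next
      h <- heterogen_test(psi, cases, ctls,
                          min_samples = config$min_samples,
                          alpha = config$alpha,
                          aberrant_control_median =
                            config$aberrant_control_median,
                          n_perm = config$n_perm, seed = config$seed)
      h$disease <- dis
      h$tissue <- tis
      het[[paste(dis, tis, sep = ".")]] <- h
    }
  }
  het_all <- do.call(rbind, het)
  rownames(het_all) <- NULL
  write.table(het_all, out("heterogen_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  profile <- summarize_cell_types(cohort$expr, cohort$cells,
                                  group = "control")
  markers <- call_markers(profile, mode = "strict",
                          log2fc_cut = config$marker_log2fc,
                          pct1_cut = config$marker_pct1,
                          pct2_cut = config$marker_pct2)
  write.table(markers, out("markers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  comp <- composition_summary(cohort$cells)
  write.table(comp$per_group, out("composition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  jg <- setNames(cohort$counts$junctions$gene_id,
                 cohort$counts$junctions$junction_id)
  bio <- nominate_biomarkers(het_all, markers, jg,
                             disease_celltype = config$disease_celltype,
                             excluded_tissues = config$excluded_tissues,
                             psi = psi)
  write.table(bio, out("biomarkers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  patients <- meta$sample[meta$group %in% names(config$disease_celltype)]
  labels <- setNames(meta$group[match(patients, meta$sample)], patients)
  split <- split_train_test(patients, labels[patients],
                            config$test_fraction, config$seed)
  report_rf <- train_and_evaluate(
    psi, labels, split, markers, jg,
    disease_celltype = config$disease_celltype, ntree = config$ntree,
    seed = config$seed, excluded_tissues = config$excluded_tissues,
    min_samples = config$min_samples, alpha = config$alpha,
    aberrant_control_median = config$aberrant_control_median,
    n_perm = config$n_perm)
  cv <- cross_validate(
    psi, labels, k = config$k_folds, markers, jg,
    disease_celltype = config$disease_celltype, ntree = config$ntree,
    seed = config$seed, excluded_tissues = config$excluded_tissues,
    min_samples = config$min_samples, alpha = config$alpha,
    aberrant_control_median = config$aberrant_control_median,
    n_perm = config$n_perm)
  write.table(report_rf$roc, out("roc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  canon <- canonical_transcripts(cohort$annotation)
  ab_truth <- cohort$truth[startsWith(cohort$truth$class, "aberrant_up"), ,
                           drop = FALSE]
  jdf <- cohort$counts$junctions
  effects <- list()
  ptc_calls <- list()
  for (i in seq_len(nrow(ab_truth))) {
    jid <- ab_truth$junction_id[i]
    j <- jdf[jdf$junction_id == jid, , drop = FALSE]
    model <- canon[[ab_truth$gene_id[i]]]
    if (is.null(model)) next
    ab <- reconstruct_aberrant_transcript(model, j, cohort$genome)
    ab$orfs <- enumerate_orfs(ab$mature, min_aa = config$min_orf_aa)
    pt <- predict_ptc(ab, model, nmd_nt = config$nmd_nt)
    effects[[jid]] <- ab
    ptc_calls[[jid]] <- pt
  }
  eff_tab <- data.frame(
    junction_id = names(effects),
    transcript_id = vapply(effects, function(x) x$transcript_id, ""),
    mature_length = vapply(effects, function(x) nchar(x$mature), 0),
    n_orfs = vapply(effects, function(x) nrow(x$orfs), 0),
    ptc = vapply(ptc_calls, function(x) as.logical(x$ptc), NA),
    stop_to_last_junction_nt = vapply(ptc_calls,
                                      function(x) as.numeric(x$distance),
                                      0),
    stringsAsFactors = FALSE)
  write.table(eff_tab, out("aberrant_transcripts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  proteome <- reference_proteome(canon, cohort$genome)
  db <- build_peptide_database(effects, proteome,
                               missed = config$digest_missed,
                               len_range = config$digest_len,
                               fasta_path = out("peptide_db.fasta"))
  write.table(db$peptides, out("novel_peptides.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ab_j <- jdf[jdf$junction_id %in% ab_truth$junction_id, , drop = FALSE]
  bf <- binding_fraction(ab_j, cohort$peaks, flank_nt = config$flank_nt)
  write.table(bf, out("binding_fractions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  files <- sort(list.files(config$output_dir, recursive = TRUE,
                           full.names = TRUE))
  files <- files[!grepl("manifest\\.json$|report\\.md$", files)]
  manifest <- list(
    seed = config$seed,
    config_hash = hash_object(
      unclass(config)[setdiff(names(config), "output_dir")]),
    package_version = as.character(utils::packageVersion("splicemark")),
    files = as.list(setNames(unname(tools::md5sum(files)),
                             sub(paste0(config$output_dir, "/?"), "",
                                 files))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  report <- list(
    n_junctions = nrow(jdf),
    n_tested = sum(het_all$call != "unquantified") / length(het),
    n_changed = sum(het_all$call %in% c("aberrant_up", "normal_up",
                                        "down")),
    n_aberrant_up = sum(het_all$call == "aberrant_up"),
    n_strict_markers = sum(markers$strict),
    n_biomarkers = nrow(bio),
    holdout_auc = report_rf$auc,
    cv_mean_auc = cv$mean_auc,
    ptc_fraction = ptc_fraction(ptc_calls),
    binding_fractions = bf,
    biomarkers = bio, heterogen = het_all, markers = markers,
    classifier = report_rf, cv = cv, effects = eff_tab,
    peptides = db$peptides, manifest = manifest,
    output_dir = config$output_dir)
  class(report) <- "run_report"
  lines <- c("# splicemark run report", "",
             sprintf("- junctions: %d", report$n_junctions),
             sprintf("- aberrant_up calls: %d", report$n_aberrant_up),
             sprintf("- strict markers: %d", report$n_strict_markers),
             sprintf("- biomarkers nominated: %d", report$n_biomarkers),
             sprintf("- held-out AUC: %.3f", report$holdout_auc),
             sprintf("- CV mean AUC: %.3f", report$cv_mean_auc),
             sprintf("- PTC fraction: %.3f", report$ptc_fraction))
  writeLines(lines, out("report.md"))
  report
}

#' Translate the canonical CDS of every gene into a reference proteome
#' @param canon named list gene -> `transcript_model` (CDS required)
#' @param genome named `DNAStringSet`
#' @return named character vector of protein sequences
#' @export
reference_proteome <- function(canon, genome) {
  out <- character(0)
  for (g in names(canon)) {
    m <- canon[[g]]
    if (is.na(m$cds_start)) next
    mat <- extract_transcript_sequence(m, genome)
    tr <- translate_frame(mat, m$cds_start)
    if (!is.na(tr$peptide) && nzchar(tr$peptide))
      out[paste0(g, ".protein")] <- tr$peptide
  }
  out
}

# md5 of an R object via its deparsed representation
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}
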