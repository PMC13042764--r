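# Shared fixtures, memoised across test files. The reference cohort uses
# the package's default design under a fixed seed; expensive products
# (PSI, heterogen calls, markers, the full pipeline run) are computed once.

.fixtures <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

shared_design <- function() cohort_design(seed = 42)

shared_cohort <- function() memo("cohort", simulate_cohort(shared_design()))

shared_psi <- function() memo("psi", compute_psi(shared_cohort()$counts))

# heterogen calls per disease x tissue, rbind'ed with disease/tissue cols
shared_het <- function() memo("het", {
  psi <- shared_psi()
  meta <- psi$metadata
  out <- list()
  for (dis in c("ALS", "FTD")) {
    for (tis in unique(meta$tissue)) {
      h <- heterogen_test(
        psi,
        meta$sample[meta$group == dis & meta$tissue == tis],
        meta$sample[meta$group == "control" & meta$tissue == tis],
        seed = 42)
      h$disease <- dis
      h$tissue <- tis
      out[[paste(dis, tis)]] <- h
    }
  }
  do.call(rbind, out)
})

shared_profile <- function() memo("profile", {
  co <- shared_cohort()
  summarize_cell_types(co$expr, co$cells, group = "control")
})

shared_markers <- function() memo("markers",
                                  call_markers(shared_profile(),
                                               mode = "strict"))

shared_pipeline <- function() memo("pipeline", {
  cfg <- default_run_config(seed = 42,
                            output_dir = file.path(tempdir(),
                                                   "splicemark_shared"))
  run_pipeline(cfg, design = shared_design())
})

# a small, fast design for unit tests
small_design <- function(seed = 7) {
  cohort_design(seed = seed, n_genes = 40, n_aberrant = 6,
                event_mix = c(cryptic_ss = 4, exon_skip = 1, utr3 = 1),
                n_normal_up = 4, n_null_alt = 20,
                extra_markers = c(Neuron = 2, Oligodendrocyte = 2,
                                  Astrocyte = 1, Microglia = 1),
                cells_per_sample = 60)
}

# forge a psi_matrix from an explicit junction x sample value matrix
forge_psi <- function(values, metadata) {
  if (is.null(colnames(values))) colnames(values) <- metadata$sample
  jid <- rownames(values)
  parts <- strsplit(jid, "[:-]")
  junctions <- splice_junctions(
    vapply(parts, `[`, "", 1),
    as.integer(vapply(parts, `[`, "", 2)),
    as.integer(vapply(parts, `[`, "", 3)),
    vapply(parts, `[`, "", 4))
  structure(list(psi = values, lsv_id = setNames(jid, jid),
                 junctions = junctions, metadata = metadata,
                 min_coverage = 10), class = "psi_matrix")
}
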