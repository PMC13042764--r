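#!/usr/bin/env Rscript
# Stage 3 — cell-type profiles, strict markers, enrichment, composition.
#
# Summarises the single-nucleus matrix over control nuclei, calls strict
# one-vs-rest markers (log2FC > 1, pct1 > 0.7, pct2 < 0.1), tests the
# splicing-altered gene sets for cell-type enrichment (Fisher), and
# writes composition summaries.

suppressPackageStartupMessages(library(splicemark))

expr_tab <- read.delim("results/cohort/expression.tsv",
                       check.names = FALSE)
expr <- as.matrix(expr_tab[, -1])
rownames(expr) <- expr_tab$gene_id
cells <- read.delim("results/cohort/cell_metadata.tsv")

profile <- summarize_cell_types(expr, cells, group = "control")
markers <- call_markers(profile, mode = "strict")
write.table(markers, "results/markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
st <- markers[markers$strict, ]
message("strict markers: ", nrow(st), " (",
        paste(sprintf("%s %d", names(table(st$cell_type)),
                      table(st$cell_type)), collapse = ", "), ")")

# enrichment of each disease's splicing-altered genes per cell type
het <- read.delim("results/heterogen_results.tsv")
truth <- read.delim("results/cohort/truth_table.tsv")
jcm <- read_junction_counts("results/cohort/junction_counts.tsv",
                            "results/cohort/sample_metadata.tsv")
annotation <- read_gene_annotation("results/cohort/annotation.gtf")
jg <- assign_junction_genes(jcm$junctions, annotation)
universe <- rownames(expr)
enr <- list()
for (dis in c("ALS", "FTD")) {
  genes <- unique(jg[het$junction_id[het$call == "aberrant_up" &
                                       het$disease == dis]])
  genes <- genes[!is.na(genes) & nzchar(genes)]
  for (ct in unique(st$cell_type)) {
    r <- fisher_enrichment(genes, st$gene[st$cell_type == ct], universe)
    enr[[paste(dis, ct)]] <- data.frame(
      disease = dis, cell_type = ct, odds_ratio = r$odds_ratio,
      p_value = r$p_value)
  }
}
enr <- do.call(rbind, enr)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (dis in c("ALS", "FTD")) {
  sub <- enr[enr$disease == dis, ]
  message(dis, " splicing genes most enriched in: ",
          sub$cell_type[which.max(sub$odds_ratio)],
          sprintf(" (OR %.1f)", max(sub$odds_ratio)))
}

comp <- composition_summary(cells)
write.table(comp$per_group, "results/composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
# the low-oligodendrocyte ALS subgroup (60% lowest), as a worked example
ps <- comp$per_sample
als <- ps[ps$group == "ALS" & ps$cell_type == "Oligodendrocyte", ]
low <- select_low_fraction_subgroup(
  setNames(als$proportion, als$sample), 0.6)
message("ALS-low subgroup (60% lowest oligodendrocyte fraction): ",
        length(low), " of ", nrow(als), " samples")
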