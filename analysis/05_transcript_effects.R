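#!/usr/bin/env Rscript
# Stage 5 — aberrant transcripts, PTC prediction, peptide database.
#
# Reconstructs the transcript implied by each aberrant junction (splice
# out all annotated introns untouched by the event, plus the aberrant
# intron), enumerates ORFs in all three forward frames, applies the
# 50-nt NMD boundary rule, and merges tryptic peptides of novel ORFs
# with the reference proteome into the MS search database.

suppressPackageStartupMessages(library(splicemark))

genome <- read_genome("results/cohort/genome.fa")
annotation <- read_gene_annotation("results/cohort/annotation.gtf")
truth <- read.delim("results/cohort/truth_table.tsv")
jcm <- read_junction_counts("results/cohort/junction_counts.tsv",
                            "results/cohort/sample_metadata.tsv")
jdf <- jcm$junctions

canon <- canonical_transcripts(annotation)
ab_truth <- truth[startsWith(truth$class, "aberrant_up"), ]
effects <- list()
ptc <- list()
for (i in seq_len(nrow(ab_truth))) {
  jid <- ab_truth$junction_id[i]
  model <- canon[[ab_truth$gene_id[i]]]
  ab <- reconstruct_aberrant_transcript(
    model, jdf[jdf$junction_id == jid, ], genome)
  ab$orfs <- enumerate_orfs(ab$mature, min_aa = 7)
  effects[[jid]] <- ab
  ptc[[jid]] <- predict_ptc(ab, model, nmd_nt = 50)
}
tab <- data.frame(
  junction_id = names(effects),
  event_type = ab_truth$event_type,
  mature_length = vapply(effects, function(x) nchar(x$mature), 0),
  n_orfs = vapply(effects, function(x) nrow(x$orfs), 0),
  ptc = vapply(ptc, function(x) as.logical(x$ptc), NA),
  distance_nt = vapply(ptc, function(x) as.numeric(x$distance), 0))
write.table(tab, "results/aberrant_transcripts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("PTC fraction: %.2f (%d of %d with a defined call)",
                ptc_fraction(ptc), sum(tab$ptc, na.rm = TRUE),
                sum(!is.na(tab$ptc))))
print(table(tab$event_type, tab$ptc, dnn = c("event", "PTC")))

proteome <- reference_proteome(canon, genome)
db <- build_peptide_database(effects, proteome,
                             fasta_path = "results/peptide_db.fasta")
write.table(db$peptides, "results/novel_peptides.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "peptide database: %d entries (%d reference proteins); %d distinct novel tryptic peptides",
  length(db$fasta), length(proteome),
  length(unique(db$peptides$sequence[db$peptides$is_novel]))))
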