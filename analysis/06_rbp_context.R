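#!/usr/bin/env Rscript
# Stage 6 — RBP binding context of the aberrant junctions.
#
# Loads the CLIP-like peak BEDs and asks, for each RBP, what fraction of
# planted aberrant junctions carry a peak within +/-150 nt of either
# splice site; then the TDP-43-anchored co-binding summary with CELF2
# and PTBP1.

suppressPackageStartupMessages(library(splicemark))

truth <- read.delim("results/cohort/truth_table.tsv")
jcm <- read_junction_counts("results/cohort/junction_counts.tsv",
                            "results/cohort/sample_metadata.tsv")
ab <- jcm$junctions[jcm$junctions$junction_id %in%
                      truth$junction_id[startsWith(truth$class,
                                                   "aberrant_up")], ]

beds <- list.files("results/cohort/peaks", full.names = TRUE)
peaks <- lapply(beds, read_peaks)
names(peaks) <- vapply(peaks, function(p) p$rbp_name, "")

bf <- binding_fraction(ab, peaks, flank_nt = 150)
write.table(bf, "results/binding_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("binding fractions over ", nrow(ab), " aberrant junctions:")
for (i in seq_len(nrow(bf)))
  message(sprintf("  %-8s %.2f", bf$rbp[i], bf$fraction[i]))

M <- cobinding_matrix(ab, peaks, c("TARDBP", "CELF2", "PTBP1"))
write.table(cbind(junction_id = rownames(M), as.data.frame(M)),
            "results/cobinding_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf(
  "of %d TDP-43-bound junctions, %d are co-bound by CELF2 or PTBP1",
  sum(M[, "TARDBP"]), attr(M, "cobinding_count")))
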