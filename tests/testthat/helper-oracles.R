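# Independent brute-force oracles used to validate the implementations.
# These deliberately share no code with the package internals.

# TNOM by direct definition: try every threshold (midpoints between all
# distinct pooled values plus outer sentinels), both orientations
oracle_tnom_stat <- function(a, b) {
  pooled <- sort(unique(c(a, b)))
  thr <- c(min(pooled) - 1,
           if (length(pooled) > 1)
             (head(pooled, -1) + tail(pooled, -1)) / 2,
           max(pooled) + 1)
  best <- Inf
  for (t in thr) {
    m1 <- sum(a > t) + sum(b <= t)   # A low / B high
    m2 <- sum(b > t) + sum(a <= t)   # B low / A high
    best <- min(best, m1, m2)
  }
  as.integer(best)
}

# exact permutation p by enumerating every label assignment
oracle_tnom_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  obs <- oracle_tnom_stat(a, b)
  sets <- combn(n, na)
  hits <- 0
  for (i in seq_len(ncol(sets))) {
    ia <- sets[, i]
    s <- oracle_tnom_stat(pooled[ia], pooled[-ia])
    if (s <= obs) hits <- hits + 1
  }
  hits / ncol(sets)
}

# ORF enumeration by scanning every substring: start at ATG, end at the
# first in-frame stop, no internal stop
oracle_orfs <- function(seq, min_aa = 1) {
  codon_aa <- as.character(Biostrings::GENETIC_CODE)
  names(codon_aa) <- names(Biostrings::GENETIC_CODE)
  n <- nchar(seq)
  out <- list()
  for (i in seq_len(max(n - 5, 0))) {
    if (substring(seq, i, i + 2) != "ATG") next
    j <- i
    pep <- ""
    ok <- TRUE
    repeat {
      if (j + 2 > n) { ok <- FALSE; break }
      cod <- substring(seq, j, j + 2)
      aa <- codon_aa[cod]
      if (is.na(aa)) { ok <- FALSE; break }
      if (aa == "*") break
      pep <- paste0(pep, aa)
      j <- j + 3
    }
    if (ok && nchar(pep) >= min_aa)
      out[[length(out) + 1]] <- data.frame(
        start = i - 1L, end = j + 2L, peptide = pep,
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0),
               peptide = character(0), stringsAsFactors = FALSE)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

binding_calls_of <- function(junctions, peaks, flank_nt) {
  vapply(seq_len(nrow(junctions)), function(i)
    junction_binding(junctions[i, ], peaks, flank_nt), NA)
}

# single-intron gene whose stop sits `dist` nt upstream of the last
# exon-exon junction of the (annotation-equivalent) aberrant transcript
make_ptc_toy <- function(dist) {
  utr5 <- 30
  cds_len <- 90
  stop_end <- utr5 + cds_len              # mature coordinate of stop end
  junction_pos <- stop_end + dist         # = end of exon 1
  exon2_len <- 150
  mature <- paste0(
    random_seq(utr5), "ATG",
    paste(rep("GCT", cds_len / 3 - 2), collapse = ""), "TAA",
    random_seq(junction_pos - stop_end + exon2_len))
  intron <- paste0("GT", random_seq(96), "AG")
  pre <- paste0(substring(mature, 1, junction_pos), intron,
                substring(mature, junction_pos + 1, nchar(mature)))
  genome <- c(chrZ = pre)
  model <- transcript_model(
    "t", "g", "chrZ", "+",
    rbind(c(0, junction_pos),
          c(junction_pos + 100, nchar(pre))),
    cds_start = utr5, cds_end = stop_end)
  j <- splice_junctions("chrZ", junction_pos, junction_pos + 100, "+")
  list(model = model, genome = genome, junction = j[1, ])
}
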