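#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rbeta rbinom rgamma rmultinom rnorm
#'   rpois runif t.test wilcox.test dhyper predict setNames complete.cases
#' @importFrom utils read.delim write.table head tail combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical junction identifier
#'
#' Junction equality throughout the package is by
#' `(chrom, intron_start, intron_end, strand)`; this builds the
#' corresponding string key, e.g. `"chr1:100-200:+"`.
#'
#' @param chrom chromosome name(s)
#' @param intron_start 0-based inclusive first intronic base
#' @param intron_end 0-based exclusive position past the last intronic base
#' @param strand `"+"` or `"-"`
#' @return character vector of junction keys
#' @export
junction_id <- function(chrom, intron_start, intron_end, strand) {
  paste0(chrom, ":", intron_start, "-", intron_end, ":", strand)
}

#' Build a splice-junction table
#'
#' The pipeline's atomic unit: a genomic intron interval with strand and an
#' optional gene assignment, in 0-based half-open coordinates (intron_start
#' is the first intronic base, intron_end one past the last).
#'
#' @param chrom,intron_start,intron_end,strand,gene_id vectors, recycled to
#'   a common length
#' @return data.frame with columns `junction_id`, `chrom`, `intron_start`,
#'   `intron_end`, `strand`, `gene_id`
#' @export
splice_junctions <- function(chrom, intron_start, intron_end, strand,
                             gene_id = "") {
  df <- data.frame(
    chrom = as.character(chrom),
    intron_start = as.integer(intron_start),
    intron_end = as.integer(intron_end),
    strand = as.character(strand),
    gene_id = as.character(gene_id),
    stringsAsFactors = FALSE
  )
  if (any(df$intron_start >= df$intron_end))
    stop("intron_start must be < intron_end for every junction")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- cbind(
    junction_id = junction_id(df$chrom, df$intron_start, df$intron_end,
                              df$strand),
    df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

# clamp numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# deterministic child seed, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reverse complement of a plain character string
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
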