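# RBP binding context of splice junctions: flank-window overlap against
# CLIP-like peak intervals, per-RBP binding fractions, and co-binding
# matrices. Windows are strand-agnostic, half-open, clipped at 0.

# window overlap test for many junctions against one peak table
binding_calls <- function(junctions, peaks, flank_nt) {
  stopifnot(flank_nt >= 1)
  n <- nrow(junctions)
  if (n == 0 || nrow(peaks) == 0) return(rep(FALSE, n))
  # peaks on chromosomes no junction uses can never bind (not an error)
  peaks <- peaks[peaks$chrom %in% junctions$chrom, , drop = FALSE]
  if (nrow(peaks) == 0) return(rep(FALSE, n))
  win <- data.frame(
    chrom = rep(junctions$chrom, 2),
    start = pmax(0L, c(junctions$intron_start - flank_nt,
                       junctions$intron_end - flank_nt)),
    end = c(junctions$intron_start + flank_nt,
            junctions$intron_end + flank_nt))
  w <- GenomicRanges::GRanges(win$chrom,
                              IRanges::IRanges(win$start + 1L, win$end))
  p <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$start + 1L,
                                               peaks$end))
  hit <- IRanges::overlapsAny(w, p, minoverlap = 1L)
  hit[seq_len(n)] | hit[n + seq_len(n)]
}

#' Does any peak bind a junction's splice-site flanks?
#'
#' TRUE iff a peak overlaps (>= 1 shared base, half-open) the window
#' `[site - flank, site + flank)` around either the 5' or the 3' splice
#' site on the junction's chromosome. Peaks on other chromosomes simply
#' do not bind (no error).
#'
#' @param junction one-row junction data.frame
#' @param peaks an `rbp_peaks` object
#' @param flank_nt window half-width in nt (default 150)
#' @return logical
#' @export
junction_binding <- function(junction, peaks, flank_nt = 150) {
  binding_calls(as.data.frame(junction), peaks$peaks, flank_nt)[1]
}

#' Per-RBP binding fraction over a junction set
#'
#' @param junctions junction data.frame (non-empty)
#' @param peak_sets list of `rbp_peaks`
#' @param flank_nt window half-width (default 150)
#' @return data.frame `rbp`, `fraction`, `n_bound`, sorted by descending
#'   fraction
#' @export
binding_fraction <- function(junctions, peak_sets, flank_nt = 150) {
  if (nrow(junctions) == 0) stop("empty junction list")
  rows <- lapply(peak_sets, function(ps) {
    hit <- binding_calls(junctions, ps$peaks, flank_nt)
    data.frame(rbp = ps$rbp_name, fraction = mean(hit),
               n_bound = sum(hit), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fraction, out$rbp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Junction x RBP co-binding matrix
#'
#' Boolean matrix of binding calls for the selected RBPs, with a summary
#' of how many junctions bound by the anchor RBP are also bound by at
#' least one co-factor.
#'
#' @param junctions junction data.frame
#' @param peak_sets named list of `rbp_peaks`
#' @param rbps RBP names to include (first is the anchor unless `anchor`
#'   given); unknown names error
#' @param anchor anchor RBP (default `rbps[1]`)
#' @param flank_nt window half-width (default 150)
#' @return object of class `binding_matrix`: logical junction x RBP
#'   matrix with attributes `flank_nt`, `anchor`, `cobinding_count`
#' @export
cobinding_matrix <- function(junctions, peak_sets, rbps,
                             anchor = rbps[1], flank_nt = 150) {
  have <- vapply(peak_sets, function(ps) ps$rbp_name, "")
  unknown <- setdiff(rbps, have)
  if (length(unknown) > 0)
    stop("unknown RBP name(s): ", paste(unknown, collapse = ", "))
  M <- vapply(rbps, function(r) {
    ps <- peak_sets[[match(r, have)]]
    binding_calls(junctions, ps$peaks, flank_nt)
  }, logical(nrow(junctions)))
  M <- matrix(M, nrow = nrow(junctions),
              dimnames = list(junctions$junction_id, rbps))
  co <- setdiff(rbps, anchor)
  cob <- if (length(co) > 0)
    sum(M[, anchor] & rowSums(M[, co, drop = FALSE]) > 0) else 0L
  structure(M, class = c("binding_matrix", class(M)), flank_nt = flank_nt,
            anchor = anchor, cobinding_count = as.integer(cob))
}
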