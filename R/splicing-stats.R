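# PSI quantification over local splicing variations (LSVs) and the
# differential-splicing statistics: the TNOM permutation statistic, the
# three-test heterogeneity rule for patient cohorts, the pooled two-group
# Fisher comparison for cell-line designs, and the positivity rate.

#' Assign junctions to local splicing variations
#'
#' Junctions sharing a donor splice site (the intron start on `+`, the
#' intron end on `-`) form an LSV; junctions whose donor is unique are
#' regrouped by shared acceptor; the remainder are singleton LSVs. Every
#' junction belongs to exactly one LSV.
#'
#' @param junctions junction data.frame (see [splice_junctions()])
#' @return character vector of LSV ids, parallel to `junctions` rows
#' @export
assign_lsvs <- function(junctions) {
  donor <- ifelse(junctions$strand == "+", junctions$intron_start,
                  junctions$intron_end)
  acceptor <- ifelse(junctions$strand == "+", junctions$intron_end,
                     junctions$intron_start)
  dkey <- paste0("D:", junctions$chrom, ":", donor, ":", junctions$strand)
  akey <- paste0("A:", junctions$chrom, ":", acceptor, ":",
                 junctions$strand)
  lsv <- dkey
  shared_d <- dkey %in% dkey[duplicated(dkey)]
  rest <- which(!shared_d)
  if (length(rest) > 0) {
    ak <- akey[rest]
    shared_a <- ak %in% ak[duplicated(ak)]
    lsv[rest[shared_a]] <- ak[shared_a]
    lsv[rest[!shared_a]] <- paste0("S:", junctions$junction_id[rest[!shared_a]])
  }
  lsv
}

#' Compute PSI from junction counts
#'
#' PSI(j, s) = count(j, s) / sum of counts over j's LSV in sample s, when
#' that denominator reaches `min_coverage`; otherwise missing (`NA`).
#' Singleton LSVs get PSI 1 when covered. Within each LSV and sample,
#' non-missing PSI values sum to 1.
#'
#' @param jcm a `junction_count_matrix`
#' @param min_coverage minimum LSV read total per sample (default 10)
#' @return object of class `psi_matrix`: list with `psi` (junction x
#'   sample matrix, `NA` = missing), `lsv_id`, `junctions`, `metadata`,
#'   `min_coverage`
#' @export
compute_psi <- function(jcm, min_coverage = 10) {
  stopifnot(min_coverage >= 1)
  lsv <- assign_lsvs(jcm$junctions)
  totals <- rowsum(jcm$counts, group = lsv, reorder = FALSE)
  denom <- totals[match(lsv, rownames(totals)), , drop = FALSE]
  psi <- jcm$counts / denom
  psi[denom < min_coverage] <- NA_real_
  dimnames(psi) <- dimnames(jcm$counts)
  structure(list(psi = psi, lsv_id = setNames(lsv,
                                              jcm$junctions$junction_id),
                 junctions = jcm$junctions, metadata = jcm$metadata,
                 min_coverage = min_coverage),
            class = "psi_matrix")
}

#' Write a PSI matrix to TSV
#' @param psi a `psi_matrix`
#' @param path output file (`NA` written for missing)
#' @return `path`, invisibly
#' @export
write_psi_matrix <- function(psi, path) {
  out <- cbind(junction_id = psi$junctions$junction_id,
               lsv_id = unname(psi$lsv_id),
               as.data.frame(psi$psi, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# TNOM statistic for a label assignment over values sorted ascending:
# minimum, over all thresholds between distinct values (and the two
# trivial all-one-side thresholds), of misclassified samples, taking the
# better of the two group-side orientations.
tnom_stat_sorted <- function(lab_sorted, valid_cuts, n_a, n_b) {
  cumA <- cumsum(lab_sorted)          # group-A members at or below cut
  ca <- c(0L, cumA)[valid_cuts + 1L]  # cuts indexed 0..n
  cb <- valid_cuts - ca
  m1 <- (n_a - ca) + cb               # A above / B below are mistakes
  m2 <- (n_b - cb) + ca
  min(m1, m2)
}

# cut positions k (0..n) lying between distinct sorted values
valid_cut_positions <- function(sorted_vals) {
  n <- length(sorted_vals)
  if (n == 0) return(integer(0))
  interior <- which(diff(sorted_vals) > 0)
  c(0L, interior, n)
}

#' Total number of mistakes (TNOM) test
#'
#' TNOM is the minimum number of misclassified samples achievable by any
#' single threshold on the pooled values (best of both orientations). The
#' p-value is P(TNOM <= observed) under uniform permutation of the group
#' labels over the pooled values: exact by enumeration of all label
#' assignments when `choose(n_a + n_b, n_a) <= max_exact`, otherwise by
#' `n_perm` seeded label permutations with add-one smoothing
#' `p = (b + 1) / (m + 1)`.
#'
#' If all pooled values are identical the statistic degenerates to
#' `min(n_a, n_b)` with p = 1.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2)
#' @param n_perm permutations when enumeration is infeasible
#' @param seed seed for the permutation path
#' @param max_exact enumeration bound on `choose(n, n_a)`
#' @param cache optional environment memoising the permutation null
#'   distribution of the statistic, which depends only on the group sizes
#'   and the tie structure (valid threshold positions) of the pooled
#'   values — not on the values themselves
#' @return list with `tnom` (integer) and `p`
#' @export
tnom_test <- function(values_a, values_b, n_perm = 10000, seed = 1,
                      max_exact = 50000, cache = NULL) {
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (n_a < 2 || n_b < 2) stop("each group needs >= 2 values")
  pooled <- c(values_a, values_b)
  n <- n_a + n_b
  ord <- order(pooled)
  sorted_vals <- pooled[ord]
  lab <- as.integer(c(rep(1L, n_a), rep(0L, n_b))[ord])
  if (sorted_vals[1] == sorted_vals[n])
    return(list(tnom = min(n_a, n_b), p = 1))
  cuts <- valid_cut_positions(sorted_vals)
  obs <- tnom_stat_sorted(lab, cuts, n_a, n_b)

  exact <- choose(n, n_a) <= max_exact
  key <- paste(n_a, n_b, exact, paste(cuts, collapse = "."), sep = "|")
  stats <- if (!is.null(cache)) cache[[key]] else NULL
  if (is.null(stats)) {
    lkey <- paste("L", n, n_a, exact, sep = "|")
    L <- if (!is.null(cache)) cache[[lkey]] else NULL
    if (is.null(L)) {
      L <- if (exact) {
        assign_idx <- combn(n, n_a)
        L0 <- matrix(0L, n, ncol(assign_idx))
        L0[assign_idx + (col(assign_idx) - 1L) * n] <- 1L
        L0
      } else {
        tnom_perm_labels(n, n_a, n_perm, seed)
      }
      if (!is.null(cache)) cache[[lkey]] <- L
    }
    stats <- tnom_stats_matrix(L, cuts, n_a, n_b)
    if (!is.null(cache)) cache[[key]] <- stats
  }
  p <- if (exact) mean(stats <= obs) else
    (sum(stats <= obs) + 1) / (length(stats) + 1)
  list(tnom = as.integer(obs), p = p)
}

# seeded matrix of permuted label assignments (n x n_perm, 1 = group A)
tnom_perm_labels <- function(n, n_a, n_perm, seed) {
  set.seed(seed)
  L <- matrix(0L, n, n_perm)
  for (b in seq_len(n_perm)) L[sample.int(n, n_a), b] <- 1L
  L
}

# vectorised TNOM over columns of a 0/1 label matrix (rows follow the
# sorted pooled values)
tnom_stats_matrix <- function(L, cuts, n_a, n_b) {
  n <- nrow(L)
  B <- ncol(L)
  v <- as.vector(L)
  cv <- cumsum(v)
  offs <- rep(c(0, cv[seq(n, by = n, length.out = B)][-B]), each = n)
  cumA <- matrix(cv - offs, n, B)
  res <- rep.int(min(n_a, n_b), B)  # covers the k = 0 cut
  for (k in setdiff(cuts, 0L)) {
    ca <- cumA[k, ]
    cb <- k - ca
    res <- pmin(res, (n_a - ca) + cb, (n_b - cb) + ca)
  }
  res
}

# one two-sided test triple on non-missing PSI; returns p-values clamped
# into (0, 1]
three_tests <- function(a, b, n_perm, seed, perm_cache = NULL) {
  p_t <- tryCatch(t.test(a, b)$p.value, error = function(e) 1)
  p_w <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  p_n <- tnom_test(a, b, n_perm = n_perm, seed = seed,
                   cache = perm_cache)$p
  c(p_tnom = max(min(p_n, 1), .Machine$double.xmin),
    p_ttest = max(min(ifelse(is.na(p_t), 1, p_t), 1),
                  .Machine$double.xmin),
    p_wilcoxon = max(min(ifelse(is.na(p_w), 1, p_w), 1),
                     .Machine$double.xmin))
}

#' Heterogeneity test over a patient cohort
#'
#' Per junction, computes a Welch t-test, a two-sided Wilcoxon rank-sum
#' test and the TNOM permutation test on non-missing PSI of the two
#' groups. A junction is "changed" when all three p-values are below
#' `alpha`; changed junctions are `up` when the case median exceeds the
#' control median and `down` otherwise; up-regulated junctions with a
#' control median strictly below `aberrant_control_median` are called
#' `aberrant_up`, the rest `normal_up`. Junctions with fewer than
#' `min_samples` non-missing values in either group are `unquantified`.
#'
#' @param psi a `psi_matrix`
#' @param case_samples,control_samples disjoint character vectors of
#'   sample ids
#' @param min_samples minimum non-missing per group (default 3)
#' @param alpha per-test significance threshold (default 0.05)
#' @param aberrant_control_median control-median PSI threshold separating
#'   aberrant from normally used junctions (default 0.05)
#' @param n_perm,seed TNOM permutation settings
#' @return data.frame: `junction_id`, `n_case`, `n_control`, `p_tnom`,
#'   `p_ttest`, `p_wilcoxon`, `median_case`, `median_control`, `call`
#'   (one of `aberrant_up`, `normal_up`, `down`, `unchanged`,
#'   `unquantified`)
#' @export
heterogen_test <- function(psi, case_samples, control_samples,
                           min_samples = 3, alpha = 0.05,
                           aberrant_control_median = 0.05,
                           n_perm = 10000, seed = 1) {
  if (length(intersect(case_samples, control_samples)) > 0)
    stop("case and control samples must be disjoint")
  stopifnot(all(c(case_samples, control_samples) %in%
                  colnames(psi$psi)))
  X <- psi$psi
  perm_cache <- new.env(parent = emptyenv())
  res <- vector("list", nrow(X))
  for (j in seq_len(nrow(X))) {
    a <- X[j, case_samples]
    b <- X[j, control_samples]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    med_a <- if (length(a)) median(a) else NA_real_
    med_b <- if (length(b)) median(b) else NA_real_
    if (length(a) < min_samples || length(b) < min_samples) {
      res[[j]] <- list(NA_real_, NA_real_, NA_real_, med_a, med_b,
                       "unquantified", length(a), length(b))
      next
    }
    pooled <- c(a, b)
    if (max(pooled) == min(pooled)) {
      res[[j]] <- list(1, 1, 1, med_a, med_b, "unchanged",
                       length(a), length(b))
      next
    }
    pv <- three_tests(a, b, n_perm, seed, perm_cache)
    call <- if (all(pv < alpha)) {
      if (med_a > med_b) {
        if (med_b < aberrant_control_median) "aberrant_up" else "normal_up"
      } else "down"
    } else "unchanged"
    res[[j]] <- list(pv[[1]], pv[[2]], pv[[3]], med_a, med_b, call,
                     length(a), length(b))
  }
  out <- data.frame(
    junction_id = psi$junctions$junction_id,
    n_case = vapply(res, function(x) x[[7]], 0L),
    n_control = vapply(res, function(x) x[[8]], 0L),
    p_tnom = vapply(res, function(x) x[[1]], 0),
    p_ttest = vapply(res, function(x) x[[2]], 0),
    p_wilcoxon = vapply(res, function(x) x[[3]], 0),
    median_case = vapply(res, function(x) x[[4]], 0),
    median_control = vapply(res, function(x) x[[5]], 0),
    call = vapply(res, function(x) x[[6]], ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-group pooled junction comparison
#'
#' For two-condition designs (e.g. knockdown vs negative control),
#' replicates are pooled by summing counts; per junction the PSI of each
#' condition is the pooled count ratio over its LSV, `delta_psi` is case
#' minus control, and the p-value is a two-sided Fisher's exact test on
#' the 2x2 table `[junction count, rest-of-LSV count] x condition`.
#' A junction is significant when `p < alpha` and `|delta_psi| >
#' delta_cut`; `is_novel` flags junctions whose intron interval is absent
#' from the annotation's introns.
#'
#' @param jcm a `junction_count_matrix`
#' @param case_samples,control_samples sample ids of the two conditions
#' @param annotation list of `transcript_model` (for novelty)
#' @param min_coverage minimum pooled LSV coverage per condition
#' @param alpha significance threshold on p (default 0.01)
#' @param delta_cut threshold on `|delta_psi|` (default 0.1)
#' @return data.frame: `junction_id`, `psi_case`, `psi_control`,
#'   `delta_psi`, `p_value`, `is_novel`, `significant`, `quantified`
#' @export
two_group_delta_psi <- function(jcm, case_samples, control_samples,
                                annotation, min_coverage = 10,
                                alpha = 0.01, delta_cut = 0.1) {
  lsv <- assign_lsvs(jcm$junctions)
  pool <- function(samples)
    as.integer(round(rowSums(jcm$counts[, samples, drop = FALSE])))
  ca <- pool(case_samples)
  co <- pool(control_samples)
  tot_a <- as.vector(rowsum(ca, lsv, reorder = FALSE))
  names(tot_a) <- unique(lsv)
  tot_o <- as.vector(rowsum(co, lsv, reorder = FALSE))
  names(tot_o) <- unique(lsv)
  den_a <- tot_a[lsv]
  den_o <- tot_o[lsv]
  ann_ids <- annotation_junctions(annotation)$junction_id
  quant <- den_a >= min_coverage & den_o >= min_coverage
  psi_a <- ifelse(quant, ca / den_a, NA_real_)
  psi_o <- ifelse(quant, co / den_o, NA_real_)
  dpsi <- psi_a - psi_o
  p <- rep(NA_real_, length(ca))
  for (j in which(quant)) {
    tab <- matrix(c(ca[j], den_a[j] - ca[j], co[j], den_o[j] - co[j]), 2)
    p[j] <- stats::fisher.test(tab)$p.value
  }
  data.frame(
    junction_id = jcm$junctions$junction_id,
    psi_case = psi_a, psi_control = psi_o, delta_psi = dpsi,
    p_value = p,
    is_novel = !(jcm$junctions$junction_id %in% ann_ids),
    significant = quant & !is.na(p) & p < alpha & abs(dpsi) > delta_cut,
    quantified = quant, stringsAsFactors = FALSE)
}

#' Positivity rate of a junction in patients
#'
#' Fraction of patient samples whose PSI lies strictly above the 75th
#' percentile of the control PSI distribution (linear-interpolation
#' quantile, index `h = p * (n - 1)` on the sorted values). Missing PSI is
#' excluded from both sets.
#'
#' @param psi_patients,psi_controls numeric vectors (controls: >= 4
#'   non-missing values required)
#' @param probs quantile level (default 0.75)
#' @return rate in `[0, 1]`
#' @export
positivity_rate <- function(psi_patients, psi_controls, probs = 0.75) {
  pc <- psi_controls[!is.na(psi_controls)]
  pp <- psi_patients[!is.na(psi_patients)]
  if (length(pc) < 4) stop("need >= 4 non-missing control values")
  if (length(pp) == 0) stop("no non-missing patient values")
  thr <- unname(quantile(pc, probs, type = 7))
  mean(pp > thr)
}

#' Splice-site dinucleotides of a junction
#'
#' Returns the first two and last two intronic bases in transcription
#' direction, so canonical junctions give `c("GT", "AG")` on either
#' strand.
#'
#' @param junction one-row junction data.frame (or list with `chrom`,
#'   `intron_start`, `intron_end`, `strand`)
#' @param genome named `DNAStringSet` or named character vector
#' @return named character vector `c(donor=, acceptor=)`
#' @export
splice_site_dinucleotides <- function(junction, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  s <- junction$intron_start
  e <- junction$intron_end
  if (e - s < 4) stop("intron shorter than 4 nt")
  chr <- as.character(genome[[junction$chrom]])
  if (e > nchar(chr)) stop("junction beyond chromosome bounds")
  left <- substring(chr, s + 1, s + 2)
  right <- substring(chr, e - 1, e)
  if (junction$strand == "+") {
    c(donor = left, acceptor = right)
  } else {
    c(donor = revcomp_chr(right), acceptor = revcomp_chr(left))
  }
}
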