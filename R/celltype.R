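# Cell-type expression summaries from single-nucleus counts, strict and
# enriched marker calling, the Neuron-to-Oligo score, Fisher enrichment of
# gene sets in cell-type-specific genes, and cell-composition statistics.

#' Summarise expression per cell type
#'
#' Cells are library-size-normalised to `scale_factor` counts, log1p
#' transformed, then averaged per gene per cell type over cells of the
#' designated control-like group. Detection is the fraction of cells with
#' a raw count above zero.
#'
#' @param expr genes x cells count matrix
#' @param cells data.frame with `cell_id`, `cell_type` and optionally
#'   `group`
#' @param group control-like group to summarise over (`NULL` = all cells)
#' @param scale_factor library-size target (default 10,000)
#' @return object of class `celltype_profile`: list with `mean_expr` and
#'   `pct_detected` (genes x cell types), `n_cells` per type,
#'   `scale_factor`
#' @export
summarize_cell_types <- function(expr, cells, group = NULL,
                                 scale_factor = 1e4) {
  if (nrow(expr) == 0 || ncol(expr) == 0) stop("empty expression matrix")
  stopifnot(identical(colnames(expr), cells$cell_id))
  if (!is.null(group)) {
    keep <- cells$group == group
    if (!any(keep)) stop("no cells in group ", group)
    expr <- expr[, keep, drop = FALSE]
    cells <- cells[keep, , drop = FALSE]
  }
  types <- sort(unique(cells$cell_type))
  lib <- colSums(expr)
  empty_cells <- lib == 0
  lib[empty_cells] <- 1
  norm <- log1p(t(t(expr) / lib) * scale_factor)
  mean_expr <- matrix(0, nrow(expr), length(types),
                      dimnames = list(rownames(expr), types))
  pct <- mean_expr
  n_cells <- setNames(integer(length(types)), types)
  drop_types <- character(0)
  for (ct in types) {
    idx <- which(cells$cell_type == ct)
    n_cells[ct] <- length(idx)
    if (length(idx) == 0) {
      drop_types <- c(drop_types, ct)
      next
    }
    mean_expr[, ct] <- rowMeans(norm[, idx, drop = FALSE])
    pct[, ct] <- rowMeans(expr[, idx, drop = FALSE] > 0)
  }
  if (length(drop_types) > 0) {
    warning("dropping cell type(s) with 0 cells: ",
            paste(drop_types, collapse = ", "))
    keep <- setdiff(types, drop_types)
    mean_expr <- mean_expr[, keep, drop = FALSE]
    pct <- pct[, keep, drop = FALSE]
    n_cells <- n_cells[keep]
  }
  structure(list(mean_expr = mean_expr, pct_detected = pct,
                 n_cells = n_cells, scale_factor = scale_factor,
                 norm = norm, cell_type = cells$cell_type),
            class = "celltype_profile")
}

#' Call cell-type marker genes
#'
#' One-vs-rest per gene per cell type on the profile's normalised
#' expression: `log2fc = log2((mu_in + eps) / (mu_out + eps))` with
#' `mu_out` the pooled mean over all other cells; `pct1` is detection in
#' the target type and `pct2` the maximum detection among the other
#' types; p from a two-sided Wilcoxon rank-sum over cells. Strict mode
#' requires `log2fc > 1`, `pct1 > 0.7` and `pct2 < 0.1` (all strict
#' inequalities); enriched mode requires `log2fc > 1` and `p < 0.05`.
#'
#' @param profile a `celltype_profile` from [summarize_cell_types()]
#' @param mode `"strict"` or `"enriched"`
#' @param eps pseudocount for fold changes (default 0.01)
#' @param log2fc_cut,pct1_cut,pct2_cut,alpha thresholds
#' @return data.frame: `gene`, `cell_type`, `log2fc`, `pct1`, `pct2`,
#'   `p_value`, `strict`/`enriched` flag column named after the mode
#' @export
call_markers <- function(profile, mode = c("strict", "enriched"),
                         eps = 0.01, log2fc_cut = 1, pct1_cut = 0.7,
                         pct2_cut = 0.1, alpha = 0.05) {
  mode <- match.arg(mode)
  types <- colnames(profile$mean_expr)
  if (length(types) < 2) stop("need >= 2 cell types")
  genes <- rownames(profile$mean_expr)
  norm <- profile$norm
  ct_of <- profile$cell_type
  rows <- list()
  for (ct in types) {
    in_idx <- which(ct_of == ct)
    out_idx <- which(ct_of != ct)
    mu_in <- profile$mean_expr[, ct]
    mu_out <- rowMeans(norm[, out_idx, drop = FALSE])
    l2fc <- log2((mu_in + eps) / (mu_out + eps))
    pct1 <- profile$pct_detected[, ct]
    pct2 <- apply(profile$pct_detected[, setdiff(types, ct),
                                       drop = FALSE], 1, max)
    pv <- vapply(genes, function(g) {
      suppressWarnings(
        wilcox.test(norm[g, in_idx], norm[g, out_idx],
                    exact = FALSE)$p.value)
    }, 0)
    pv[is.na(pv)] <- 1
    flag <- if (mode == "strict") {
      l2fc > log2fc_cut & pct1 > pct1_cut & pct2 < pct2_cut
    } else {
      l2fc > log2fc_cut & pv < alpha
    }
    df <- data.frame(gene = genes, cell_type = ct, log2fc = l2fc,
                     pct1 = pct1, pct2 = pct2, p_value = pv,
                     stringsAsFactors = FALSE)
    df[[mode]] <- flag
    rows[[ct]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neuron-to-Oligo score
#'
#' `log2((mean of per-neuron-type mean expression + eps) /
#' (oligodendrocyte mean expression + eps))`, attributing a gene's bulk
#' signal to neurons (positive) or oligodendrocytes (negative).
#'
#' @param profile a `celltype_profile`
#' @param gene gene id
#' @param neuron_types cell-type names averaged as the neuron group
#' @param oligo_type oligodendrocyte cell-type name
#' @param eps pseudocount (default 0.01)
#' @return numeric score
#' @export
neuron_to_oligo_score <- function(profile, gene,
                                  neuron_types = "Neuron",
                                  oligo_type = "Oligodendrocyte",
                                  eps = 0.01) {
  if (!gene %in% rownames(profile$mean_expr))
    stop("gene ", gene, " absent from profile")
  mu_n <- mean(profile$mean_expr[gene, neuron_types])
  mu_o <- mean(profile$mean_expr[gene, oligo_type])
  log2((mu_n + eps) / (mu_o + eps))
}

#' Fisher enrichment of a gene set in an annotation set
#'
#' Builds the 2x2 table `a = |query & annot|`, `b = |query \\ annot|`,
#' `c = |annot \\ query|`, `d = |universe \\ (query | annot)|`. The odds
#' ratio is the sample `ad / bc` with Haldane correction (+0.5 to every
#' cell) when any cell is zero; the two-sided p-value is the sum of
#' hypergeometric probabilities of all tables (at fixed margins) no more
#' probable than the observed one.
#'
#' @param query_genes,annotation_genes,universe_genes character vectors;
#'   query and annotation must be subsets of the universe
#' @return list with `table` (named a/b/c/d), `odds_ratio`, `p_value`
#' @export
fisher_enrichment <- function(query_genes, annotation_genes,
                              universe_genes) {
  if (length(universe_genes) == 0) stop("empty universe")
  q <- unique(query_genes)
  an <- unique(annotation_genes)
  u <- unique(universe_genes)
  if (!all(q %in% u) || !all(an %in% u))
    stop("query and annotation must be subsets of the universe")
  a <- length(intersect(q, an))
  b <- length(setdiff(q, an))
  cc <- length(setdiff(an, q))
  dd <- length(u) - a - b - cc
  or <- if (any(c(a, b, cc, dd) == 0)) {
    (a + 0.5) * (dd + 0.5) / ((b + 0.5) * (cc + 0.5))
  } else {
    a * dd / (b * cc)
  }
  list(table = c(a = a, b = b, c = cc, d = dd), odds_ratio = or,
       p_value = hypergeom_two_sided(a, b, cc, dd))
}

# two-sided Fisher p by hypergeometric tail summation at fixed margins
hypergeom_two_sided <- function(a, b, cc, dd) {
  m <- a + cc          # annotation positives
  n <- b + dd          # annotation negatives
  k <- a + b           # query size
  lo <- max(0, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  # relative tolerance guards against float ties, as in fisher.test
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Cell-composition summary
#'
#' Per-sample cell-type proportions and per-group median and quartiles of
#' each type's proportion. Samples with zero cells are excluded with a
#' warning.
#'
#' @param cells data.frame with `cell_type`, `sample`, `group`
#' @return list with `per_sample` (data.frame `sample`, `group`,
#'   `cell_type`, `proportion`; proportions sum to 1 per sample) and
#'   `per_group` (data.frame `group`, `cell_type`, `q25`, `median`,
#'   `q75`)
#' @export
composition_summary <- function(cells) {
  if (nrow(cells) == 0) stop("no cells")
  samples <- unique(cells$sample)
  tab <- table(cells$sample, cells$cell_type)
  zero <- rownames(tab)[rowSums(tab) == 0]
  if (length(zero) > 0)
    warning("excluding sample(s) with 0 cells: ",
            paste(zero, collapse = ", "))
  prop <- tab / rowSums(tab)
  grp <- cells$group[match(rownames(prop), cells$sample)]
  per_sample <- data.frame(
    sample = rep(rownames(prop), ncol(prop)),
    group = rep(grp, ncol(prop)),
    cell_type = rep(colnames(prop), each = nrow(prop)),
    proportion = as.vector(prop), stringsAsFactors = FALSE)
  rows <- list()
  for (g in unique(grp)) {
    for (ct in colnames(prop)) {
      v <- prop[grp == g, ct]
      qs <- quantile(v, c(0.25, 0.5, 0.75), type = 7)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, cell_type = ct, q25 = qs[[1]], median = qs[[2]],
        q75 = qs[[3]], stringsAsFactors = FALSE)
    }
  }
  per_group <- do.call(rbind, rows)
  rownames(per_group) <- NULL
  list(per_sample = per_sample, per_group = per_group)
}

#' Select the samples with the lowest proportion of a cell type
#'
#' Returns the `floor(fraction * n)` samples with the lowest proportion;
#' ties at the boundary are broken by lexicographic sample id.
#'
#' @param proportions named numeric vector (names = sample ids)
#' @param fraction fraction in (0, 1]
#' @return character vector of selected sample ids
#' @export
select_low_fraction_subgroup <- function(proportions, fraction) {
  if (length(proportions) == 0) stop("empty input")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- floor(fraction * length(proportions))
  ord <- order(proportions, names(proportions))
  names(proportions)[ord][seq_len(n)]
}
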