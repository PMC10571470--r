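#' Single-sample GSEA score
#'
#' Rank-weighted running-sum enrichment score per sample. Genes are ranked
#' by expression within each sample (the highest-expressed gene gets rank N,
#' ties broken by gene name); walking down the ranking, the in-set running
#' fraction accumulates |rank|^alpha normalized by the set's total rank
#' weight, and the out-of-set fraction accumulates uniform steps
#' 1/(N - |S|). The score is the sum over all positions of the difference
#' between the two running fractions (the sum statistic, not the maximum
#' deviation), with no cohort-wide rescaling — so scores are comparable only
#' within one matrix.
#'
#' @param expr an [expression_matrix()] (any units; the score is rank-based
#'   and invariant to strictly monotone transforms within a sample).
#' @param set a character vector of gene symbols, or a
#'   [gene_set_collection()] (first set used unless `set_name` given).
#' @param alpha rank-weight exponent (default 0.25, the usual single-sample
#'   GSEA choice).
#' @param set_name set to use when `set` is a collection.
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(expr, set, alpha = 0.25, set_name = NULL) {
  stopifnot(inherits(expr, "expression_matrix"), alpha > 0)
  rs <- resolve_set(set, set_name)
  mg <- match_genes(rs$genes, expr$genes)
  if (length(mg$idx) < 2) {
    stop_cafscape(sprintf("fewer than 2 set genes found in the matrix; missing: %s",
                          paste(mg$missing, collapse = ", ")))
  }
  m <- as_dense(expr)
  n <- nrow(m)
  in_set <- logical(n)
  in_set[mg$idx] <- TRUE
  n_out <- n - sum(in_set)
  apply_cols(m, function(v) {
    # descending expression; ties broken by gene name
    ord <- order(-v, expr$genes)
    ranks <- n:1                       # rank N at the top of the walk
    inset_walk <- in_set[ord]
    w <- ifelse(inset_walk, ranks^alpha, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!inset_walk) / n_out
    sum(p_in - p_out)
  }, expr$cells)
}

# apply over columns returning a named vector
apply_cols <- function(m, f, names) {
  stats::setNames(vapply(seq_len(ncol(m)), function(j) f(m[, j]), 0), names)
}

#' AUCell-style recovery-curve score
#'
#' Per cell, genes are ranked by decreasing expression (ties broken by a
#' seeded random shuffle, as in AUCell); the recovery curve counts set genes
#' among the top ranks 1..T with T = `ceiling(top_fraction * N)`. The score
#' is the area under this step curve divided by the maximal attainable area
#' (all set genes at the very top), so it lies in [0, 1].
#'
#' @param expr an [expression_matrix()].
#' @param set gene set (vector or [gene_set_collection()]).
#' @param top_fraction fraction of the ranking examined (default 0.05, the
#'   AUCell default).
#' @param seed integer seed for tie-breaking.
#' @param set_name set to use when `set` is a collection.
#' @return Named numeric vector of per-cell scores in [0, 1].
#' @export
aucell_score <- function(expr, set, top_fraction = 0.05, seed = 1L,
                         set_name = NULL) {
  stopifnot(inherits(expr, "expression_matrix"),
            top_fraction > 0, top_fraction < 1)
  rs <- resolve_set(set, set_name)
  mg <- match_genes(rs$genes, expr$genes)
  if (length(mg$idx) == 0) stop_cafscape("no set genes found in the matrix")
  m <- as_dense(expr)
  n <- nrow(m)
  t_top <- ceiling(top_fraction * n)
  if (t_top < 1) stop_cafscape("top_fraction selects no genes",
                               "cafscape_parameter_error")
  in_set <- logical(n)
  in_set[mg$idx] <- TRUE
  s_size <- sum(in_set)
  max_area <- sum(pmin(seq_len(t_top), s_size))
  set.seed(as.integer(seed))
  tie_break <- stats::runif(n)
  apply_cols(m, function(v) {
    ord <- order(-v, tie_break)
    hits <- cumsum(in_set[ord][seq_len(t_top)])
    sum(hits) / max_area
  }, expr$cells)
}

#' Geometric-mean signature score
#'
#' Per sample, the geometric mean of the set genes' expression:
#' `exp(mean(log(x + eps)))`. The default pseudo-offset `eps = 0.01`
#' guards against zeros and is deliberately not subtracted afterwards; with
#' `eps = 0` and all-positive input this is the classical geometric mean
#' (e.g. cytolytic activity as the geometric mean of GZMA and PRF1).
#'
#' @param expr an [expression_matrix()] with non-negative values.
#' @param set gene set.
#' @param eps pseudo-offset added before the log (default 0.01).
#' @param set_name set to use when `set` is a collection.
#' @return Named numeric vector of per-sample scores.
#' @export
geometric_mean_score <- function(expr, set, eps = 0.01, set_name = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  rs <- resolve_set(set, set_name)
  mg <- match_genes(rs$genes, expr$genes)
  if (length(mg$idx) == 0) {
    stop_cafscape(sprintf("no set genes found in the matrix; missing: %s",
                          paste(rs$genes, collapse = ", ")))
  }
  m <- as_dense(expr)[mg$idx, , drop = FALSE]
  stats::setNames(exp(colMeans(log(m + eps))), expr$cells)
}

#' Mean-expression signature score
#'
#' Per sample, the arithmetic mean of the set genes' expression — the
#' convention used for TLS, IFN-gamma (6-gene) and expanded-immune
#' (18-gene) signatures.
#'
#' @inheritParams geometric_mean_score
#' @return Named numeric vector of per-sample scores.
#' @export
mean_score <- function(expr, set, set_name = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  rs <- resolve_set(set, set_name)
  mg <- match_genes(rs$genes, expr$genes)
  if (length(mg$idx) == 0) {
    stop_cafscape(sprintf("no set genes found in the matrix; missing: %s",
                          paste(rs$genes, collapse = ", ")))
  }
  m <- as_dense(expr)[mg$idx, , drop = FALSE]
  stats::setNames(colMeans(m), expr$cells)
}

#' Weighted-sum signature score with housekeeping normalization
#'
#' Per sample, each signature gene's expression is centred by subtracting
#' the mean expression of the housekeeping genes in that sample; the score
#' is the weighted sum of the centred values — the construction of the
#' T-cell-inflamed gene-expression-profile score.
#'
#' @param expr an [expression_matrix()].
#' @param set a [gene_set_collection()] with weights, or a character vector
#'   (then `weights` must be supplied).
#' @param housekeeping character vector of housekeeping gene symbols.
#' @param weights per-gene weights if `set` is a plain vector.
#' @param set_name set to use when `set` is a collection.
#' @return Named numeric vector of per-sample scores.
#' @export
weighted_sum_score <- function(expr, set, housekeeping, weights = NULL,
                               set_name = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  rs <- resolve_set(set, set_name)
  w <- rs$weights %||% weights
  if (is.null(w) || length(w) != length(rs$genes)) {
    stop_cafscape("a weight is required for every signature gene")
  }
  mg <- match_genes(rs$genes, expr$genes)
  if (length(mg$missing) > 0) {
    stop_cafscape(sprintf("signature gene(s) missing from the matrix: %s",
                          paste(mg$missing, collapse = ", ")))
  }
  hk <- match_genes(housekeeping, expr$genes)
  if (length(hk$idx) == 0) stop_cafscape("no housekeeping genes found")
  m <- as_dense(expr)
  hk_mean <- colMeans(m[hk$idx, , drop = FALSE])
  sig <- m[mg$idx, , drop = FALSE]
  # sum_g w_g * (x_gj - hk_mean_j) = sum_g w_g x_gj - hk_mean_j * sum(w)
  stats::setNames(colSums(sig * w) - sum(w) * hk_mean, expr$cells)
}

#' Median split of per-sample scores
#'
#' Samples scoring above the median go to the "high" group; samples at or
#' below the median go to "low" (ties at the median are assigned to low by
#' convention, for determinism).
#'
#' @param scores named numeric vector of per-sample scores.
#' @return A list of class `group_split` with `group` (named character,
#'   `"high"`/`"low"`) and `threshold` (the median).
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop_cafscape("need at least 2 samples")
  if (length(unique(scores)) == 1) {
    stop_cafscape("degenerate split: all scores identical")
  }
  med <- stats::median(scores)
  structure(list(group = ifelse(scores > med, "high", "low"),
                 threshold = med),
            class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf("<group_split> high: %d, low: %d (median threshold %.4g)\n",
              sum(x$group == "high"), sum(x$group == "low"), x$threshold))
  invisible(x)
}

#' Inflammatory-CAF score pipeline
#'
#' End-to-end construction of the iCAF-style score: take the top `n_markers`
#' upregulated markers of `group` from a single-cell marker table, score a
#' bulk cohort with [ssgsea_score()] on those markers, and split samples at
#' the median score.
#'
#' @param markers a `marker_table` from [find_markers()].
#' @param group the cell type whose markers define the signature.
#' @param bulk_expr bulk cohort [expression_matrix()].
#' @param n_markers number of top markers (default 10).
#' @param alpha ssGSEA rank-weight exponent.
#' @return A list with `signature`, `scores` and `split` (a `group_split`).
#' @export
icaf_score_pipeline <- function(markers, group, bulk_expr, n_markers = 10,
                                alpha = 0.25) {
  sig <- top_markers(markers, group, n_markers)
  if (length(sig) < 2) {
    stop_cafscape(sprintf("fewer than 2 significant markers for group '%s'",
                          group))
  }
  scores <- ssgsea_score(bulk_expr, sig, alpha = alpha)
  list(signature = sig, scores = scores, split = median_split(scores))
}
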