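#' Regulon-activity matrix with cell-type annotation
#'
#' Container for AUCell-style regulon activity scores (RAS): a non-negative
#' regulon x cell matrix plus a per-cell cell-type label.
#'
#' @param activity non-negative numeric matrix, regulons in rows, cells in
#'   columns (dimnames required).
#' @param cell_type character vector of per-cell labels, length `ncol(activity)`.
#' @return An object of class `regulon_activity`.
#' @export
regulon_activity <- function(activity, cell_type) {
  if (is.null(rownames(activity)) || is.null(colnames(activity))) {
    stop_cafscape("activity matrix needs regulon and cell dimnames")
  }
  if (min(activity) < 0) stop_cafscape("regulon activity must be non-negative")
  if (length(cell_type) != ncol(activity)) {
    stop_cafscape("cell_type must have one label per cell")
  }
  structure(list(activity = activity, cell_type = as.character(cell_type)),
            class = "regulon_activity")
}

#' @export
print.regulon_activity <- function(x, ...) {
  cat(sprintf("<regulon_activity> %d regulon(s) x %d cell(s), %d type(s)\n",
              nrow(x$activity), ncol(x$activity),
              length(unique(x$cell_type))))
  invisible(x)
}

#' Shannon entropy in bits
#'
#' H(p) = -sum p_i log2 p_i, with the convention 0 * log 0 = 0.
#'
#' @param p a probability vector: non-negative, summing to 1 (within 1e-6).
#' @return Entropy in bits.
#' @export
#' @examples
#' entropy(c(0.5, 0.5))          # 1 bit
#' entropy(c(0.25, 0.25, 0.25, 0.25))  # 2 bits
entropy <- function(p) {
  if (any(p < 0)) stop_cafscape("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop_cafscape("probabilities must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Jensen-Shannon divergence (base 2)
#'
#' JSD(p, q) = H((p + q)/2) - (H(p) + H(q))/2 with base-2 logarithms, so the
#' divergence lies in [0, 1], reaching 1 exactly for distributions with
#' disjoint supports.
#'
#' @param p,q probability vectors of equal length.
#' @return JSD in [0, 1].
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) {
    stop_cafscape("distributions must have equal length")
  }
  d <- entropy((p + q) / 2) - (entropy(p) + entropy(q)) / 2
  min(max(d, 0), 1)  # clamp tiny floating-point excursions
}

#' Regulon specificity score
#'
#' RSS(R, C) = 1 - sqrt(JSD(P^R, P^C)), where P^R is the regulon's activity
#' vector normalized to sum 1 over cells and P^C is the cell-type indicator
#' vector normalized the same way. RSS is 1 when the regulon is active
#' uniformly in exactly the member cells, and 0 when its activity is
#' entirely outside the type.
#'
#' @param activity non-negative activity over cells (at least one nonzero).
#' @param indicator logical/0-1 membership vector, same length.
#' @return RSS in [0, 1], or `NA` (with a warning) for all-zero activity.
#' @export
rss <- function(activity, indicator) {
  if (length(activity) != length(indicator)) {
    stop_cafscape("activity and indicator must have equal length")
  }
  indicator <- as.numeric(indicator != 0)
  if (sum(indicator) == 0) stop_cafscape("indicator has no member cells")
  if (any(activity < 0)) stop_cafscape("activity must be non-negative")
  if (sum(activity) == 0) {
    warning("all-zero activity vector: RSS undefined", call. = FALSE)
    return(NA_real_)
  }
  p_r <- activity / sum(activity)
  p_c <- indicator / sum(indicator)
  1 - sqrt(jsd(p_r, p_c))
}

#' RSS for every regulon and cell type
#'
#' Computes the regulon specificity score for each (regulon, cell type)
#' pair and flags, per cell type, the top 5 regulons by RSS (ties broken by
#' regulon name). Regulons with all-zero activity are skipped with a
#' warning; cell types with no cells are skipped.
#'
#' @param ras a [regulon_activity()].
#' @param n_top number of top regulons to flag per type (default 5).
#' @return A data frame of class `rss_matrix`: `regulon`, `cell_type`,
#'   `rss`, `rank_in_type`, `top` (logical).
#' @export
rss_matrix <- function(ras, n_top = 5) {
  stopifnot(inherits(ras, "regulon_activity"))
  types <- sort(unique(ras$cell_type))
  act <- ras$activity
  zero <- Matrix::rowSums(act) == 0
  if (any(zero)) {
    warning(sprintf("skipping %d all-zero regulon(s): %s", sum(zero),
                    paste(utils::head(rownames(act)[zero], 3), collapse = ", ")),
            call. = FALSE)
    act <- act[!zero, , drop = FALSE]
  }
  rows <- list()
  for (tp in types) {
    ind <- ras$cell_type == tp
    vals <- apply(act, 1L, rss, indicator = ind)
    ord <- order(-vals, names(vals))
    rk <- integer(length(vals))
    rk[ord] <- seq_along(vals)
    rows[[tp]] <- data.frame(regulon = rownames(act), cell_type = tp,
                             rss = unname(vals), rank_in_type = rk,
                             top = rk <= n_top, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("rss_matrix", "data.frame")
  res
}
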