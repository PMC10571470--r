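#' One-vs-rest rank-sum marker detection
#'
#' For every gene and every group, performs a two-sided Wilcoxon rank-sum
#' test of the group's cells against all remaining cells, computes the
#' log fold change as the difference of mean log-expression (group minus
#' rest), and applies Benjamini-Hochberg adjustment across genes within each
#' group. A gene is flagged significant when `|log2FC| > lfc_min` and
#' adjusted p < `alpha`, the conventional marker-gene thresholds.
#'
#' The rank-sum p-value is exact (no ties, fewer than 50 cells per side) or
#' uses the normal approximation with tie correction otherwise, following
#' the default behaviour of standard single-cell marker finders.
#'
#' @param expr an [expression_matrix()] with `units = "log"`.
#' @param groups character/factor of per-cell group labels, length
#'   `ncol(expr)`; every group needs at least 2 cells.
#' @param lfc_min minimum absolute log fold change (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return A data frame of class `marker_table`, one row per (gene, group):
#'   `gene`, `group`, `log2fc`, `statistic` (rank-sum W), `p`, `p_adj`,
#'   `direction` (`"up"`/`"down"`), `significant`.
#' @export
find_markers <- function(expr, groups, lfc_min = 1, alpha = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$units != "log") {
    stop_cafscape("find_markers requires log-normalized expression (units = 'log')",
                  "cafscape_units_error")
  }
  groups <- as.character(groups)
  if (length(groups) != length(expr$cells)) {
    stop_cafscape("groups must have one label per cell")
  }
  tab <- table(groups)
  if (length(tab) < 2) stop_cafscape("need at least 2 groups")
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    stop_cafscape(sprintf("group(s) with fewer than 2 cells: %s",
                          paste(small, collapse = ", ")))
  }
  m <- as_dense(expr)
  out <- vector("list", length(tab))
  for (gi in seq_along(names(tab))) {
    g <- names(tab)[gi]
    in_g <- groups == g
    lfc <- rowMeans(m[, in_g, drop = FALSE]) - rowMeans(m[, !in_g, drop = FALSE])
    res <- t(apply(m, 1L, function(v) {
      wt <- suppressWarnings(stats::wilcox.test(v[in_g], v[!in_g],
                                                alternative = "two.sided"))
      c(wt$statistic, wt$p.value)
    }))
    p_adj <- stats::p.adjust(res[, 2L], method = "BH")
    out[[gi]] <- data.frame(
      gene = expr$genes, group = g, log2fc = unname(lfc),
      statistic = unname(res[, 1L]), p = unname(res[, 2L]),
      p_adj = unname(p_adj),
      direction = ifelse(lfc >= 0, "up", "down"),
      significant = abs(lfc) > lfc_min & p_adj < alpha,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Top marker genes of a group
#'
#' Returns the `n` significant genes of `group` with the largest log fold
#' change (upregulated markers).
#'
#' @param markers a `marker_table` from [find_markers()].
#' @param group group label.
#' @param n number of genes to return.
#' @return Character vector of at most `n` gene symbols.
#' @export
top_markers <- function(markers, group, n = 10) {
  stopifnot(inherits(markers, "marker_table"))
  sub <- markers[markers$group == group & markers$significant &
                   markers$log2fc > 0, , drop = FALSE]
  sub <- sub[order(-sub$log2fc, sub$gene), , drop = FALSE]
  utils::head(sub$gene, n)
}
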