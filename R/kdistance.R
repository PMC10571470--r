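#' Spatial k-distance to a reference cell type
#'
#' For every cell, computes the arithmetic mean of the Euclidean distances to
#' its `k` nearest cells of `ref_type` within the same slice, excluding the
#' cell itself (so a reference cell never counts itself among its own
#' neighbours). Ties at the k-th neighbour are broken by reference cell_id in
#' lexicographic order, making the statistic fully deterministic. Slices with
#' fewer than `k` reference cells are skipped with a warning and flagged;
#' reference cells in a slice with exactly `k` reference cells get `NA`
#' (self-exclusion leaves only `k - 1` neighbours).
#'
#' Distances are computed by exact all-pairs evaluation in the slice's native
#' coordinate units; no approximate neighbour search is used.
#'
#' @param cells a [cell_map()].
#' @param ref_type the reference cell-type label.
#' @param k number of nearest reference neighbours (default 10, the
#'   conventional choice for spatial k-distance).
#' @return A data frame of class `k_distance_result` with columns `cell_id`,
#'   `slice_id`, `cell_type`, `k_distance` (`NA` where undefined), and
#'   attributes `ref_type`, `k`, `skipped_slices`.
#' @export
#' @examples
#' cm <- cell_map(c("r1", "r2", "r3", "q"), "s1",
#'                x = c(0, 3, 6, 0), y = c(0, 0, 0, 4),
#'                cell_type = c("ref", "ref", "ref", "query"))
#' k_distance(cm, "ref", k = 2)  # query cell: mean(4, 5) = 4.5
k_distance <- function(cells, ref_type, k = 10) {
  stopifnot(inherits(cells, "cell_map"), is_count(k))
  if (!ref_type %in% cells$cell_type) {
    stop_cafscape(sprintf("reference type '%s' absent from the cell map",
                          ref_type))
  }
  out <- rep(NA_real_, nrow(cells))
  skipped <- character()
  for (slice in unique(cells$slice_id)) {
    in_slice <- which(cells$slice_id == slice)
    ref_idx <- in_slice[cells$cell_type[in_slice] == ref_type]
    if (length(ref_idx) < k) {
      warning(sprintf("slice '%s' has %d < k = %d reference cells; skipped",
                      slice, length(ref_idx), k), call. = FALSE)
      skipped <- c(skipped, slice)
      next
    }
    # order reference cells by cell_id once; within equal distances this
    # ordering breaks ties at the k-th neighbour deterministically
    ref_idx <- ref_idx[order(cells$cell_id[ref_idx])]
    rx <- cells$x[ref_idx]
    ry <- cells$y[ref_idx]
    for (i in in_slice) {
      d <- sqrt((rx - cells$x[i])^2 + (ry - cells$y[i])^2)
      self <- which(ref_idx == i)
      if (length(self) > 0) d <- d[-self]
      if (length(d) < k) next  # ref cell in a slice with exactly k refs
      # stable sort preserves the cell_id order among tied distances
      out[i] <- mean(sort(d, method = "radix")[seq_len(k)])
    }
  }
  res <- data.frame(cell_id = cells$cell_id, slice_id = cells$slice_id,
                    cell_type = cells$cell_type, k_distance = out,
                    stringsAsFactors = FALSE)
  attr(res, "ref_type") <- ref_type
  attr(res, "k") <- k
  attr(res, "skipped_slices") <- skipped
  class(res) <- c("k_distance_result", "data.frame")
  res
}

#' Per-slice proximity ranking of cell types
#'
#' Within each slice, cell types are ordered from closest to farthest by the
#' mean spatial k-distance of their member cells to the reference type. The
#' reference type itself is excluded from the ranking; types absent from a
#' slice are simply missing from that slice's (partial) list. Ties are
#' broken alphabetically. The result can be fed directly to [rra()] to
#' obtain a consensus proximity ranking across slices.
#'
#' @inheritParams k_distance
#' @return A [ranked_lists()] whose universe is all non-reference cell types.
#' @export
celltype_proximity_ranking <- function(cells, ref_type, k = 10) {
  kd <- k_distance(cells, ref_type, k)
  kd <- kd[!is.na(kd$k_distance) & kd$cell_type != ref_type, , drop = FALSE]
  universe <- sort(unique(cells$cell_type[cells$cell_type != ref_type]))
  slices <- unique(kd$slice_id)
  lists <- lapply(slices, function(s) {
    sub <- kd[kd$slice_id == s, , drop = FALSE]
    means <- tapply(sub$k_distance, sub$cell_type, mean)
    names(means)[order(means, names(means))]
  })
  names(lists) <- slices
  ranked_lists(lists, universe = universe)
}

#' Partition cells into reference-proximal and reference-distal regions
#'
#' Per slice, the `max(1, floor(fraction * n_eligible))` eligible cells with
#' the smallest k-distance are labelled proximal; the remaining eligible
#' cells are distal. Eligible cells are those with a defined k-distance
#' whose type is not the reference type (reference cells would trivially
#' dominate the proximal decile). Ties at the cutoff are broken by
#' (k_distance, cell_id).
#'
#' @param kd a `k_distance_result` from [k_distance()].
#' @param fraction proximal fraction in (0, 1); 0.10 selects the top 10%
#'   closest cells.
#' @return A data frame of class `proximity_partition`: `cell_id`,
#'   `slice_id`, `cell_type`, `k_distance`, `region` (`"proximal"`,
#'   `"distal"`, or `NA` for ineligible cells); attribute `empty_slices`
#'   flags slices with no eligible cells.
#' @export
proximal_partition <- function(kd, fraction = 0.10) {
  stopifnot(inherits(kd, "k_distance_result"), fraction > 0, fraction < 1)
  ref_type <- attr(kd, "ref_type")
  region <- rep(NA_character_, nrow(kd))
  eligible <- !is.na(kd$k_distance) & kd$cell_type != ref_type
  empty <- character()
  for (slice in unique(kd$slice_id)) {
    idx <- which(eligible & kd$slice_id == slice)
    if (length(idx) == 0) {
      empty <- c(empty, slice)
      next
    }
    n_prox <- max(1L, floor(fraction * length(idx)))
    ord <- idx[order(kd$k_distance[idx], kd$cell_id[idx])]
    region[ord[seq_len(n_prox)]] <- "proximal"
    region[ord[-seq_len(n_prox)]] <- "distal"
  }
  res <- data.frame(cell_id = kd$cell_id, slice_id = kd$slice_id,
                    cell_type = kd$cell_type, k_distance = kd$k_distance,
                    region = region, stringsAsFactors = FALSE)
  attr(res, "ref_type") <- ref_type
  attr(res, "fraction") <- fraction
  attr(res, "empty_slices") <- empty
  class(res) <- c("proximity_partition", "data.frame")
  res
}

#' Proximal vs distal cell-type enrichment across slices
#'
#' For each cell type, computes its proportion among eligible cells within
#' the proximal and the distal region of every slice, forms the paired
#' per-slice differences d_s = prop_proximal - prop_distal, and tests them
#' with a paired t-test (t = mean(d) / (sd(d)/sqrt(m)), df = m - 1,
#' two-sided). Types observed in fewer than 2 slices are dropped with a
#' warning; types with constant nonzero differences (sd = 0) are reported
#' with p = 0 and flagged degenerate.
#'
#' @inheritParams k_distance
#' @param fraction proximal fraction passed to [proximal_partition()].
#' @return A data frame of class `enrichment_table`: `cell_type`,
#'   `n_slices`, `mean_diff`, `t`, `df`, `p`, `direction`
#'   (`"proximal-enriched"` / `"distal-enriched"`), `degenerate`.
#' @export
proximity_enrichment <- function(cells, ref_type, k = 10, fraction = 0.10) {
  part <- proximal_partition(k_distance(cells, ref_type, k), fraction)
  part <- part[!is.na(part$region), , drop = FALSE]
  slices <- unique(part$slice_id)
  types <- sort(unique(part$cell_type))
  # per slice x region proportions over eligible cells
  diffs <- matrix(NA_real_, length(types), length(slices),
                  dimnames = list(types, slices))
  for (s in slices) {
    sub <- part[part$slice_id == s, , drop = FALSE]
    if (!all(c("proximal", "distal") %in% sub$region)) next
    for (r in c("proximal", "distal")) {
      in_r <- sub$region == r
      prop <- table(factor(sub$cell_type[in_r], levels = types)) / sum(in_r)
      if (r == "proximal") diffs[, s] <- as.numeric(prop)
      else diffs[, s] <- diffs[, s] - as.numeric(prop)
    }
  }
  rows <- lapply(types, function(tp) {
    d <- diffs[tp, !is.na(diffs[tp, ])]
    m <- length(d)
    if (m < 2) {
      warning(sprintf("cell type '%s' contributes fewer than 2 slices; dropped",
                      tp), call. = FALSE)
      return(NULL)
    }
    md <- mean(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
      degen <- md != 0
      return(data.frame(cell_type = tp, n_slices = m, mean_diff = md,
                        t = if (degen) sign(md) * Inf else 0, df = m - 1,
                        p = if (degen) 0 else 1,
                        direction = if (md >= 0) "proximal-enriched" else
                          "distal-enriched",
                        degenerate = degen, stringsAsFactors = FALSE))
    }
    tstat <- md / (sdd / sqrt(m))
    data.frame(cell_type = tp, n_slices = m, mean_diff = md, t = tstat,
               df = m - 1, p = 2 * stats::pt(-abs(tstat), df = m - 1),
               direction = if (md >= 0) "proximal-enriched" else
                 "distal-enriched",
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "ref_type") <- attr(part, "ref_type")
  attr(res, "fraction") <- fraction
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' Significant rows of an enrichment table
#'
#' Convenience filter for heatmap-style reporting: keeps only cell types
#' with p below the cutoff, signed by direction.
#'
#' @param et an `enrichment_table` from [proximity_enrichment()].
#' @param alpha significance cutoff (default 0.05).
#' @return The filtered table, ordered by p.
#' @export
significant_enrichment <- function(et, alpha = 0.05) {
  stopifnot(inherits(et, "enrichment_table"))
  res <- et[et$p < alpha, , drop = FALSE]
  res[order(res$p), , drop = FALSE]
}
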