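#' A family of per-slice ranked lists
#'
#' Holds per-slice orderings (possibly partial permutations) of a shared
#' item universe, e.g. cell types ranked by spatial proximity, or
#' ligand-receptor pairs ranked by occurrence frequency.
#'
#' @param lists a list of character vectors, each without duplicates, all
#'   items drawn from the universe. Empty lists are dropped with a warning.
#' @param universe optional explicit item universe; defaults to the sorted
#'   union of all listed items.
#' @return An object of class `ranked_lists` with elements `lists`,
#'   `universe`, `provenance` (the list names).
#' @export
ranked_lists <- function(lists, universe = NULL) {
  empty <- vapply(lists, length, 0L) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d empty list(s)", sum(empty)), call. = FALSE)
    lists <- lists[!empty]
  }
  if (length(lists) == 0) stop_cafscape("no non-empty lists supplied")
  for (i in seq_along(lists)) {
    lists[[i]] <- as.character(lists[[i]])
    if (anyDuplicated(lists[[i]])) {
      stop_cafscape(sprintf("list %d contains duplicated items", i))
    }
  }
  universe <- universe %||% sort(unique(unlist(lists)))
  stray <- setdiff(unlist(lists), universe)
  if (length(stray) > 0) {
    stop_cafscape(sprintf("item(s) outside the universe: %s",
                          paste(utils::head(stray, 5), collapse = ", ")))
  }
  if (is.null(names(lists))) names(lists) <- sprintf("list%02d", seq_along(lists))
  structure(list(lists = lists, universe = as.character(universe),
                 provenance = names(lists)),
            class = "ranked_lists")
}

#' @export
print.ranked_lists <- function(x, ...) {
  cat(sprintf("<ranked_lists> %d list(s) over %d item(s)\n",
              length(x$lists), length(x$universe)))
  invisible(x)
}

#' Normalized rank matrix
#'
#' Converts ranked lists to normalized ranks r = position / |universe|
#' (1-based positions, so r lies in (0, 1]). Items missing from a list are
#' imputed at r = 1, i.e. treated as ranked last — the conservative
#' convention for partial lists.
#'
#' @param rl a [ranked_lists()].
#' @return A numeric matrix, items x lists, entries in (0, 1].
#' @export
normalize_ranks <- function(rl) {
  stopifnot(inherits(rl, "ranked_lists"))
  n_u <- length(rl$universe)
  r <- matrix(1, n_u, length(rl$lists),
              dimnames = list(rl$universe, names(rl$lists)))
  for (j in seq_along(rl$lists)) {
    lst <- rl$lists[[j]]
    r[match(lst, rl$universe), j] <- seq_along(lst) / n_u
  }
  r
}

#' Order-statistic beta scores
#'
#' For sorted normalized ranks r(1) <= ... <= r(n) of one item across n
#' lists, the k-th beta score is the probability that the k-th order
#' statistic of n iid Uniform(0,1) variables falls at or below r(k):
#' beta_k = P(U_(k) <= r(k)) = sum_{l=k}^{n} C(n,l) r(k)^l (1-r(k))^(n-l),
#' evaluated through the regularized incomplete beta function
#' (`pbeta(r, k, n - k + 1)`) for numerical stability. A small beta score
#' means the item sits unusually high across lists.
#'
#' @param sorted_r numeric vector of normalized ranks, sorted ascending,
#'   each in (0, 1].
#' @return Numeric vector of beta scores, same length as `sorted_r`.
#' @export
#' @examples
#' beta_scores(c(0.1, 0.1))  # 1 - 0.9^2 = 0.19, and 0.01
beta_scores <- function(sorted_r) {
  if (is.unsorted(sorted_r)) stop_cafscape("ranks must be sorted ascending")
  if (any(sorted_r <= 0) || any(sorted_r > 1)) {
    stop_cafscape("normalized ranks must lie in (0, 1]")
  }
  n <- length(sorted_r)
  stats::pbeta(sorted_r, seq_len(n), n - seq_len(n) + 1)
}

#' Robust rank aggregation
#'
#' Aggregates per-slice ranked lists into a consensus ranking. Each item's
#' rho is the minimum of its order-statistic [beta_scores()] across list
#' positions; the corrected p-value applies a Bonferroni factor equal to
#' the number of lists (the number of minima considered):
#' p = min(1, rho * n). Items are ordered by ascending rho, ties broken by
#' item name.
#'
#' @param rl a [ranked_lists()].
#' @return A data frame of class `rra_result`: `item`, `rho`,
#'   `p_corrected`, `consensus_rank`.
#' @export
rra <- function(rl) {
  stopifnot(inherits(rl, "ranked_lists"))
  if (length(rl$universe) == 1) {
    warning("single-item universe: consensus ranking is trivial", call. = FALSE)
  }
  r <- normalize_ranks(rl)
  n_lists <- ncol(r)
  rho <- apply(r, 1L, function(v) min(beta_scores(sort(v))))
  res <- data.frame(item = rownames(r), rho = unname(rho),
                    p_corrected = pmin(1, unname(rho) * n_lists),
                    stringsAsFactors = FALSE)
  res <- res[order(res$rho, res$item), , drop = FALSE]
  res$consensus_rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("rra_result", "data.frame")
  res
}

#' Aggregate per-slice ligand-receptor interaction frequencies
#'
#' Converts per-slice ligand-receptor occurrence counts into ranked lists
#' (descending count, ties broken by pair name) over the union universe of
#' pairs, then aggregates them with [rra()]. Pairs absent from a slice are
#' treated as ranked last in that slice.
#'
#' @param per_slice_lri named list, one element per slice: a named numeric
#'   vector of occurrence counts (names are `"LIGAND-RECEPTOR"` strings),
#'   or a data frame with columns `pair` and `count`.
#' @return An `rra_result` over the union of pairs.
#' @export
aggregate_lri <- function(per_slice_lri) {
  if (length(per_slice_lri) == 0) stop_cafscape("empty ligand-receptor input")
  counts <- lapply(per_slice_lri, function(x) {
    if (is.data.frame(x)) x <- stats::setNames(x$count, x$pair)
    if (is.null(names(x)) || any(x < 1)) {
      stop_cafscape("each slice needs named counts >= 1")
    }
    x
  })
  lists <- lapply(counts, function(x) names(x)[order(-x, names(x))])
  universe <- sort(unique(unlist(lapply(counts, names))))
  rra(ranked_lists(lists, universe = universe))
}
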