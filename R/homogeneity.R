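#' Discretize expression profiles into bins
#'
#' Per gene, expression across the analyzed cells is cut into `n_bins`
#' equal-width bins over that gene's [min, max] range (the default), or
#' equal-frequency bins behind the `method` flag. A constant gene is
#' assigned bin 0 for every cell. The bin index is
#' `min(floor((x - min)/width), n_bins - 1)`, so the maximum always lands
#' in the last bin.
#'
#' @param expr an [expression_matrix()].
#' @param genes marker genes to discretize over (must be present).
#' @param n_bins number of bins (default 10).
#' @param method `"width"` (equal-width, default) or `"frequency"`
#'   (equal-frequency quantile bins).
#' @return An integer matrix of class `discretized_profile`, cells in rows
#'   and genes in columns, entries in `0..n_bins-1`.
#' @export
discretize <- function(expr, genes, n_bins = 10,
                       method = c("width", "frequency")) {
  stopifnot(inherits(expr, "expression_matrix"), n_bins >= 2)
  method <- match.arg(method)
  mg <- match_genes(genes, expr$genes)
  if (length(mg$missing) > 0) {
    stop_cafscape(sprintf("gene(s) missing from the matrix: %s",
                          paste(mg$missing, collapse = ", ")))
  }
  m <- as_dense(expr)[mg$idx, , drop = FALSE]
  bins <- matrix(0L, ncol(m), nrow(m),
                 dimnames = list(expr$cells, expr$genes[mg$idx]))
  for (g in seq_len(nrow(m))) {
    v <- m[g, ]
    if (method == "width") {
      rng <- range(v)
      if (rng[1] == rng[2]) next  # constant gene: all bin 0
      width <- (rng[2] - rng[1]) / n_bins
      bins[, g] <- pmin(floor((v - rng[1]) / width), n_bins - 1L)
    } else {
      qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
      if (length(qs) < 2) next
      bins[, g] <- as.integer(cut(v, qs, include.lowest = TRUE)) - 1L
    }
  }
  storage.mode(bins) <- "integer"
  class(bins) <- c("discretized_profile", class(bins))
  attr(bins, "n_bins") <- as.integer(n_bins)
  bins
}

#' Normalized mutual information between two discretized cell profiles
#'
#' Treats the two cells' bin vectors over the same genes as paired samples:
#' the joint distribution p(a, b) is the fraction of genes with bin a in
#' cell x and bin b in cell y, marginals by summation; mutual information
#' and entropies use base-2 logs with 0 log 0 = 0, and
#' NMI = I(X;Y) / sqrt(H(X) H(Y)). When either profile is constant
#' (entropy 0) the NMI is defined as 0 — a constant profile carries no
#' shared information.
#'
#' @param x,y integer bin vectors of equal length (one entry per gene).
#' @param n_bins number of bins the profiles were discretized into.
#' @return NMI in [0, 1].
#' @export
pairwise_nmi <- function(x, y, n_bins = 10) {
  if (length(x) != length(y)) stop_cafscape("profiles must have equal length")
  g <- length(x)
  joint <- tabulate(x * n_bins + y + 1L, n_bins * n_bins) / g
  px <- tabulate(x + 1L, n_bins) / g
  py <- tabulate(y + 1L, n_bins) / g
  hx <- { nz <- px > 0; -sum(px[nz] * log2(px[nz])) }
  hy <- { nz <- py > 0; -sum(py[nz] * log2(py[nz])) }
  if (hx == 0 || hy == 0) return(0)
  # joint index a*n_bins + b + 1 reshapes to J[b+1, a+1] = p(a, b),
  # so the matching product of marginals is outer(py, px)
  joint_m <- matrix(joint, n_bins, n_bins)
  prod_m <- outer(py, px)
  nz <- joint_m > 0
  mi <- sum(joint_m[nz] * log2(joint_m[nz] / prod_m[nz]))
  mi / sqrt(hx * hy)
}

#' Transcriptional homogeneity by subsampled pairwise NMI
#'
#' For each sample, repeatedly subsamples `n_cells` cells (all cells when a
#' sample is smaller — small samples are kept, not dropped), computes the
#' NMI between every pair of subsampled cells over the discretized marker
#' profiles, and records the median. Replicates draw from seeded substreams
#' so the whole result is reproducible and independent of sample order.
#'
#' @param expr an [expression_matrix()] over the analyzed cells.
#' @param cells_by_sample named character/factor of per-cell sample labels.
#' @param markers marker genes used for the discretized profiles.
#' @param n_cells subsample size per replicate (default 100).
#' @param n_reps number of replicates per sample (default 100).
#' @param n_bins number of discretization bins (default 10).
#' @param seed master seed.
#' @return A data frame of class `homogeneity_result`: `sample`,
#'   `replicate`, `median_nmi`, plus attribute `n_cells`.
#' @export
homogeneity <- function(expr, cells_by_sample, markers, n_cells = 100,
                        n_reps = 100, n_bins = 10, seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(cells_by_sample) != length(expr$cells)) {
    stop_cafscape("cells_by_sample must have one label per cell")
  }
  bins <- discretize(expr, markers, n_bins = n_bins)
  samples <- sort(unique(as.character(cells_by_sample)))
  rows <- list()
  for (si in seq_along(samples)) {
    s <- samples[si]
    idx <- which(cells_by_sample == s)
    if (length(idx) < 2) {
      warning(sprintf("sample '%s' has fewer than 2 cells; skipped", s),
              call. = FALSE)
      next
    }
    med <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      set.seed(derive_seed(seed, si * 100000L + r))
      take <- if (length(idx) > n_cells) sample(idx, n_cells) else idx
      sub <- bins[take, , drop = FALSE]
      n <- nrow(sub)
      vals <- numeric(n * (n - 1) / 2)
      ct <- 0L
      for (a in seq_len(n - 1)) {
        for (b in (a + 1):n) {
          ct <- ct + 1L
          vals[ct] <- pairwise_nmi(sub[a, ], sub[b, ], n_bins)
        }
      }
      med[r] <- stats::median(vals)
    }
    rows[[s]] <- data.frame(sample = s, replicate = seq_len(n_reps),
                            median_nmi = med, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "n_cells") <- n_cells
  class(res) <- c("homogeneity_result", "data.frame")
  res
}
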