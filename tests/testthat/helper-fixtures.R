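# Shared fixture builders: everything is generated in code, no files on disk.

# A tiny expression matrix with named genes/cells.
toy_expr <- function(values, genes = NULL, cells = NULL, units = "counts") {
  genes <- genes %||% sprintf("G%02d", seq_len(nrow(values)))
  cells <- cells %||% sprintf("c%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, cells)
  expression_matrix(values, units = units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cell map on a single slice from coordinate vectors.
toy_map <- function(x, y, cell_type, slice = "s1") {
  cell_map(sprintf("c%03d", seq_along(x)), slice, x, y, cell_type)
}

# Brute-force mean distance to the k nearest reference cells, written
# independently of the package implementation (plain all-pairs scan).
brute_kdist <- function(cells, ref_type, k) {
  out <- rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ref <- cells[cells$slice_id == cells$slice_id[i] &
                   cells$cell_type == ref_type &
                   cells$cell_id != cells$cell_id[i], , drop = FALSE]
    if (nrow(ref) < k) next
    d <- sqrt((ref$x - cells$x[i])^2 + (ref$y - cells$y[i])^2)
    ord <- order(d, ref$cell_id)
    out[i] <- mean(d[ord][seq_len(k)])
  }
  out
}

# Direct binomial-sum evaluation of the order-statistic beta score.
binom_beta <- function(r, k, n) {
  sum(vapply(k:n, function(l) choose(n, l) * r^l * (1 - r)^(n - l), 0))
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p for a
# 2x2 table, matching the "sum probabilities <= observed" definition.
fisher_enum <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  xs <- max(0, col1 - (n - row1)):min(row1, col1)
  probs <- dhyper(xs, col1, n - col1, row1)
  obs <- dhyper(a, col1, n - col1, row1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact enumeration of the two-sided rank-sum p for small groups with
# distinct values: all assignments of the pooled ranks to group A.
wilcox_enum <- function(x, y) {
  n_x <- length(x); pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  combs <- utils::combn(length(pooled), n_x)
  ws <- apply(combs, 2, function(idx) sum(ranks[idx]) - n_x * (n_x + 1) / 2)
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Independent running-sum evaluation of the single-sample GSEA statistic,
# following the written definition step by step.
ssgsea_oracle <- function(values, genes, set, alpha) {
  n <- length(values)
  ord <- order(-values, genes)           # descending, ties by name
  walk <- genes[ord]
  rank_of <- n:1                         # rank N for the highest
  in_set <- walk %in% set
  denom_in <- sum(rank_of[in_set]^alpha)
  p_in <- 0; p_out <- 0; total <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + rank_of[i]^alpha / denom_in
    else p_out <- p_out + 1 / (n - sum(in_set))
    total <- total + (p_in - p_out)
  }
  total
}
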