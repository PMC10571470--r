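#' Cancer-preference odds ratios for cell subtypes
#'
#' For every combination of subtype i and cancer type j, builds the 2x2
#' contingency table (a: cells of subtype i in cancer j; b: subtype i in
#' other cancers; c: non-i subtypes in cancer j; d: non-i in other cancers)
#' and reports the sample cross-product odds ratio OR = (a d)/(b c) together
#' with the two-sided Fisher exact p-value (sum of hypergeometric
#' probabilities at or below the observed table's). When any cell of a
#' table is zero, the Haldane-Anscombe correction adds 0.5 to all four
#' cells before computing the OR (the p-value always uses the raw counts).
#'
#' @param annotations data frame with columns `subtype` and `cancer_type`
#'   (one row per cell), or two parallel vectors via `subtype` /
#'   `cancer_type` arguments.
#' @param subtype,cancer_type optional vectors used when `annotations` is
#'   missing.
#' @return A data frame of class `preference_table`: `subtype`, `cancer`,
#'   `a`, `b`, `c`, `d`, `or`, `p`, `corrected` (whether the 0.5 correction
#'   fired).
#' @export
#' @examples
#' ann <- data.frame(subtype = rep(c("iCAF", "mCAF"), c(30, 30)),
#'                   cancer_type = rep(c("BRCA", "CRC", "BRCA", "CRC"),
#'                                     c(20, 10, 10, 20)))
#' preference_or(ann)
preference_or <- function(annotations = NULL, subtype = NULL,
                          cancer_type = NULL) {
  if (!is.null(annotations)) {
    if (!all(c("subtype", "cancer_type") %in% names(annotations))) {
      stop_cafscape("annotations needs columns subtype, cancer_type",
                    "cafscape_schema_error")
    }
    subtype <- annotations$subtype
    cancer_type <- annotations$cancer_type
  }
  subtype <- as.character(subtype)
  cancer_type <- as.character(cancer_type)
  subs <- sort(unique(subtype))
  cancers <- sort(unique(cancer_type))
  if (length(subs) < 2 || length(cancers) < 2) {
    stop_cafscape("need at least 2 subtypes and 2 cancer types")
  }
  tab <- table(subtype, cancer_type)
  total <- sum(tab)
  rows <- list()
  for (i in subs) {
    for (j in cancers) {
      a <- tab[i, j]
      b <- sum(tab[i, ]) - a
      cc <- sum(tab[, j]) - a
      d <- total - a - b - cc
      corrected <- any(c(a, b, cc, d) == 0)
      or <- if (corrected) {
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
      } else {
        (a * d) / (b * cc)
      }
      p <- stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value
      rows[[paste(i, j)]] <- data.frame(
        subtype = i, cancer = j, a = as.integer(a), b = as.integer(b),
        c = as.integer(cc), d = as.integer(d), or = or, p = p,
        corrected = corrected, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("preference_table", "data.frame")
  res
}
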