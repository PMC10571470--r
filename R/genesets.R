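#' Named gene-set collection
#'
#' Holds named gene sets, optionally with per-gene weights (used by the
#' weighted-sum T-cell-inflamed score). Member lists must be non-empty and
#' weights, when present, align one-to-one with members.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param weights optional named list of numeric vectors, parallel to `sets`.
#' @return An object of class `gene_set_collection`.
#' @export
#' @examples
#' gene_set_collection(list(CYT = c("GZMA", "PRF1")))
gene_set_collection <- function(sets, weights = NULL) {
  if (length(sets) == 0 || is.null(names(sets)) || any(names(sets) == "")) {
    stop_cafscape("sets must be a non-empty named list")
  }
  for (nm in names(sets)) {
    sets[[nm]] <- as.character(sets[[nm]])
    if (length(sets[[nm]]) == 0) {
      stop_cafscape(sprintf("gene set '%s' is empty", nm))
    }
    if (!is.null(weights[[nm]]) &&
        length(weights[[nm]]) != length(sets[[nm]])) {
      stop_cafscape(sprintf("weights for set '%s' do not align with members", nm))
    }
  }
  structure(list(sets = sets, weights = weights), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s): %s\n", length(x$sets),
              paste(utils::head(names(x$sets), 5), collapse = ", ")))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated format used by MSigDB: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Parsing is delegated to
#' \pkg{fgsea} when available.
#'
#' @param path path to a `.gmt` file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                            vapply(parts, `[[`, "", 1L))
  }
  gene_set_collection(sets)
}

#' Read a weighted gene set from a two-column TSV
#'
#' Expects columns `gene` and `weight` (header required).
#'
#' @param path path to the TSV file.
#' @param name name to give the set.
#' @return A [gene_set_collection()] with one weighted set.
#' @export
read_weighted_set <- function(path, name = "weighted") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "weight") %in% names(df))) {
    stop_cafscape(sprintf("file '%s' must have columns gene, weight", path),
                  "cafscape_schema_error")
  }
  gene_set_collection(stats::setNames(list(as.character(df$gene)), name),
                      stats::setNames(list(as.numeric(df$weight)), name))
}

# Resolve one gene set (and optional weights) against a collection or a
# plain character vector.
resolve_set <- function(set, name = NULL) {
  if (inherits(set, "gene_set_collection")) {
    nm <- name %||% names(set$sets)[1]
    list(genes = set$sets[[nm]], weights = set$weights[[nm]])
  } else {
    list(genes = as.character(set), weights = NULL)
  }
}

# Case-insensitive matching of set genes into a matrix's gene universe;
# returns row indices for the matched genes and the unmatched symbols.
match_genes <- function(set_genes, universe) {
  idx <- match(upper_symbols(set_genes), upper_symbols(universe))
  list(idx = idx[!is.na(idx)], missing = set_genes[is.na(idx)])
}
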