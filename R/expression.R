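#' Gene-by-cell expression matrix
#'
#' Container for a non-negative gene x cell (or gene x sample) expression
#' matrix, tagged with its units: raw counts (`"counts"`), log-normalized
#' values (`"log"`), or continuous linear-scale values (`"linear"`, e.g. bulk
#' microarray/TPM-like data). Gene symbols must be unique after upper-casing.
#'
#' @param values numeric matrix (base or `Matrix` sparse), genes in rows and
#'   cells/samples in columns; all entries must be non-negative.
#' @param genes,cells optional identifier vectors; default to dimnames.
#' @param units one of `"counts"`, `"log"`, `"linear"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `genes`, `cells`, `units`.
#' @export
#' @examples
#' m <- matrix(c(1, 3, 0, 2), 2, dimnames = list(c("GZMA", "PRF1"), c("c1", "c2")))
#' expression_matrix(m, units = "counts")
expression_matrix <- function(values, genes = rownames(values),
                              cells = colnames(values),
                              units = c("counts", "log", "linear")) {
  units <- match.arg(units)
  if (is.null(genes) || is.null(cells)) {
    stop_cafscape("gene and cell identifiers are required (set dimnames or pass them)")
  }
  if (length(genes) != nrow(values) || length(cells) != ncol(values)) {
    stop_cafscape("identifier lists do not match matrix dimensions",
                  "cafscape_format_error")
  }
  if (prod(dim(values)) > 0 && min(values) < 0) {
    stop_cafscape("expression values must be non-negative")
  }
  genes <- as.character(genes)
  if (anyDuplicated(upper_symbols(genes))) {
    stop_cafscape("gene symbols must be unique after upper-casing")
  }
  rownames(values) <- genes
  colnames(values) <- as.character(cells)
  structure(list(values = values, genes = genes,
                 cells = as.character(cells), units = units),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells [%s]\n",
              length(x$genes), length(x$cells), x$units))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Dense numeric view of the values, used by scoring code.
as_dense <- function(expr) as.matrix(expr$values)

#' Per-cell summaries of an expression matrix
#'
#' `cell_totals()` returns total counts (UMIs) per cell, `genes_detected()`
#' the number of genes with nonzero expression per cell, and
#' `mito_fraction()` the fraction of counts on mitochondrial genes,
#' identified by the (case-insensitive) symbol prefix `MT-`.
#'
#' @param expr an [expression_matrix()].
#' @return A named numeric vector, one entry per cell.
#' @export
cell_totals <- function(expr) {
  stats::setNames(Matrix::colSums(expr$values), expr$cells)
}

#' @rdname cell_totals
#' @export
genes_detected <- function(expr) {
  stats::setNames(Matrix::colSums(expr$values > 0), expr$cells)
}

#' @rdname cell_totals
#' @export
mito_fraction <- function(expr) {
  tot <- Matrix::colSums(expr$values)
  mito <- startsWith(upper_symbols(expr$genes), "MT-")
  mt <- if (any(mito)) Matrix::colSums(expr$values[mito, , drop = FALSE]) else
    rep(0, length(tot))
  frac <- ifelse(tot > 0, mt / tot, 0)
  stats::setNames(frac, expr$cells)
}

#' Read an expression matrix
#'
#' Supports Matrix Market triplet format (`.mtx` with `genes.tsv` and
#' `barcodes.tsv` sidecars in the same directory, or explicit sidecar paths)
#' and dense CSV (genes in rows, first column gene symbols, header of cell
#' identifiers).
#'
#' @param path path to the `.mtx` or `.csv` file.
#' @param format `"auto"` (by extension), `"mtx"` or `"csv"`.
#' @param genes_path,cells_path sidecar paths for `"mtx"`; default to
#'   `genes.tsv` / `barcodes.tsv` next to `path`.
#' @param units units tag for the returned matrix.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv"),
                            genes_path = NULL, cells_path = NULL,
                            units = "counts") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  }
  if (format == "mtx") {
    genes_path <- genes_path %||% file.path(dirname(path), "genes.tsv")
    cells_path <- cells_path %||% file.path(dirname(path), "barcodes.tsv")
    m <- Matrix::readMM(path) * 1  # numeric, even for pattern matrices
    genes <- utils::read.table(genes_path, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(cells_path, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop_cafscape(sprintf(
        "sidecar dimensions (%d genes, %d cells) do not match matrix (%d x %d)",
        length(genes), length(cells), nrow(m), ncol(m)),
        "cafscape_format_error")
    }
    return(expression_matrix(m, genes, cells, units = units))
  }
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  expression_matrix(m, genes, colnames(m), units = units)
}

#' Write an expression matrix
#'
#' Dense CSV (genes in rows) or Matrix Market triplet with `genes.tsv` /
#' `barcodes.tsv` sidecars.
#'
#' @param expr an [expression_matrix()].
#' @param path output path (`.csv` or `.mtx`).
#' @param format `"auto"`, `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  }
  if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(expr$values,
                                                           sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    utils::write.table(expr$genes, file.path(dirname(path), "genes.tsv"),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(expr$cells, file.path(dirname(path), "barcodes.tsv"),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(gene = expr$genes, as.matrix(expr$values),
                     check.names = FALSE)
    colnames(df) <- c("gene", expr$cells)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Quality-control thresholds
#'
#' Default thresholds follow the common droplet scRNA-seq convention of
#' excluding cells with more than 40,000 UMIs, fewer than 500 or more than
#' 5,000 detected genes, or more than 20% mitochondrial counts. Exclusion is
#' strict: a cell exactly at a threshold is retained.
#'
#' @param max_umi maximum UMI count per cell.
#' @param min_genes,max_genes bounds on detected genes per cell.
#' @param max_mito maximum mitochondrial count fraction, in (0, 1].
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_umi = 40000, min_genes = 500,
                          max_genes = 5000, max_mito = 0.20) {
  stopifnot(min_genes < max_genes, max_mito > 0, max_mito <= 1)
  structure(list(max_umi = max_umi, min_genes = min_genes,
                 max_genes = max_genes, max_mito = max_mito),
            class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' Retains exactly the cells with UMI total `<= max_umi`, detected genes in
#' `[min_genes, max_genes]`, and mitochondrial fraction `<= max_mito`. Each
#' removed cell is reported with the first criterion it failed, checked in
#' the order umi, min_genes, max_genes, mito.
#'
#' @param expr an [expression_matrix()] of raw counts.
#' @param thr a [qc_thresholds()].
#' @return A list with `expr` (the filtered matrix) and `report`, a data
#'   frame with columns `cell_id`, `keep`, `reason` (`NA` for kept cells).
#' @export
qc_filter <- function(expr, thr = qc_thresholds()) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(thr, "qc_thresholds"))
  if (expr$units != "counts") {
    stop_cafscape("qc_filter requires raw counts (units = 'counts')",
                  "cafscape_units_error")
  }
  umi <- cell_totals(expr)
  ngene <- genes_detected(expr)
  mito <- mito_fraction(expr)
  reason <- rep(NA_character_, length(expr$cells))
  reason[is.na(reason) & umi > thr$max_umi] <- "umi"
  reason[is.na(reason) & ngene < thr$min_genes] <- "min_genes"
  reason[is.na(reason) & ngene > thr$max_genes] <- "max_genes"
  reason[is.na(reason) & mito > thr$max_mito] <- "mito"
  keep <- is.na(reason)
  report <- data.frame(cell_id = expr$cells, keep = keep, reason = reason,
                       stringsAsFactors = FALSE)
  filtered <- expression_matrix(expr$values[, keep, drop = FALSE],
                                expr$genes, expr$cells[keep],
                                units = expr$units)
  list(expr = filtered, report = report)
}
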