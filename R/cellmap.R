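#' Spatially mapped single cells
#'
#' A `cell_map` is a data frame of spatially charted single cells: one row per
#' cell with its slice (tissue section) of origin, 2-D coordinates in the
#' slice's native length units, and a cell-type label. All distance
#' computations in the package are confined within a single slice; a
#' `cell_map` may span many slices.
#'
#' @param cell_id character, cell identifiers (unique within each slice).
#' @param slice_id character, tissue-slice identifiers.
#' @param x,y numeric, finite spatial coordinates.
#' @param cell_type character, one label per cell.
#'
#' @return A data frame of class `cell_map` with columns
#'   `cell_id`, `slice_id`, `x`, `y`, `cell_type`.
#' @export
#' @examples
#' cm <- cell_map(c("c1", "c2"), "s1", c(0, 3), c(0, 4), c("iCAF", "mCAF"))
#' cm
cell_map <- function(cell_id, slice_id, x, y, cell_type) {
  df <- data.frame(cell_id = as.character(cell_id),
                   slice_id = as.character(slice_id),
                   x = as.numeric(x), y = as.numeric(y),
                   cell_type = as.character(cell_type),
                   stringsAsFactors = FALSE)
  validate_cell_map(df)
}

validate_cell_map <- function(df) {
  required <- c("cell_id", "slice_id", "x", "y", "cell_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_cafscape(sprintf("cell map is missing column(s): %s",
                          paste(missing, collapse = ", ")),
                  "cafscape_schema_error")
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    bad <- which(!is.finite(df$x) | !is.finite(df$y))[1]
    stop_cafscape(sprintf("non-finite coordinate at row %d", bad),
                  "cafscape_parse_error")
  }
  dup <- duplicated(df[, c("slice_id", "cell_id")])
  if (any(dup)) {
    stop_cafscape(sprintf("duplicated cell_id within slice '%s': %s",
                          df$slice_id[which(dup)[1]], df$cell_id[which(dup)[1]]),
                  "cafscape_schema_error")
  }
  class(df) <- c("cell_map", "data.frame")
  df
}

#' Read a cell map from CSV/TSV
#'
#' The file must carry a header with columns `cell_id`, `slice_id`, `x`, `y`,
#' `cell_type` (any order; extra columns are dropped). Row order is preserved.
#'
#' @param path path to a delimited text file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A [cell_map()].
#' @export
read_cell_map <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("cell_id", "slice_id", "x", "y", "cell_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_cafscape(sprintf("file '%s' is missing column(s): %s", path,
                          paste(missing, collapse = ", ")),
                  "cafscape_schema_error")
  }
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop_cafscape(sprintf("non-numeric %s coordinate at row %d of '%s'",
                            col, which(is.na(v))[1], path),
                    "cafscape_parse_error")
    }
    df[[col]] <- v
  }
  validate_cell_map(df[, required])
}

#' Write a cell map to CSV/TSV
#'
#' @param cells a [cell_map()].
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_cell_map <- function(cells, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  utils::write.table(as.data.frame(cells), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> %d cells, %d slice(s), %d cell type(s)\n",
              nrow(x), length(unique(x$slice_id)),
              length(unique(x$cell_type))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
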