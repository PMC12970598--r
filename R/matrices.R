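#' Expression matrix container
#'
#' A genes x cell-lines numeric matrix with a layer tag (`"mrna"` or
#' `"protein"`). Row names are gene identifiers, column names cell-line
#' identifiers; both must be unique. Missing values are allowed and expected
#' for protein layers.
#'
#' @param values Numeric matrix, genes in rows, cell lines in columns, with
#'   rownames and colnames set.
#' @param layer `"mrna"` or `"protein"`.
#' @return An object of class `omics_matrix` (a matrix with attributes).
#' @export
omics_matrix <- function(values, layer = c("mrna", "protein")) {
  layer <- match.arg(layer)
  values <- check_ids_matrix(values, "omics_matrix")
  structure(values, layer = layer, class = c("omics_matrix", "matrix", "array"))
}

#' Dependency matrix container
#'
#' A genes x cell-lines matrix of CERES-style knockout fitness scores (more
#' negative = stronger dependency).
#'
#' @param values Numeric matrix with rownames (genes) and colnames (cell
#'   lines).
#' @return An object of class `dependency_matrix`.
#' @export
dependency_matrix <- function(values) {
  values <- check_ids_matrix(values, "dependency_matrix")
  structure(values, class = c("dependency_matrix", "matrix", "array"))
}

check_ids_matrix <- function(values, what) {
  if (!is.matrix(values) || !is.numeric(values)) {
    data_error(sprintf("%s: values must be a numeric matrix", what))
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    data_error(sprintf("%s: rownames (genes) and colnames (cell lines) required",
                       what))
  }
  if (anyDuplicated(rownames(values))) {
    warning(sprintf("%s: duplicated gene ids; keeping first occurrence", what))
    values <- values[!duplicated(rownames(values)), , drop = FALSE]
  }
  if (anyDuplicated(colnames(values))) {
    warning(sprintf("%s: duplicated cell-line ids; keeping first occurrence",
                    what))
    values <- values[, !duplicated(colnames(values)), drop = FALSE]
  }
  values
}

#' Cell-line lineage annotation
#'
#' @param cell_line Character vector of cell-line identifiers.
#' @param lineage Character vector of lineage labels, same length.
#' @return A tibble with columns `cell_line`, `lineage` (class
#'   `lineage_annotation`); each cell line maps to exactly one lineage.
#' @export
lineage_annotation <- function(cell_line, lineage) {
  stopifnot(length(cell_line) == length(lineage))
  df <- tibble::tibble(cell_line = as.character(cell_line),
                       lineage = as.character(lineage))
  df <- dplyr::distinct(df)
  if (anyDuplicated(df$cell_line)) {
    bad <- unique(df$cell_line[duplicated(df$cell_line)])
    data_error(sprintf(
      "lineage_annotation: cell line(s) with conflicting lineages: %s",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  class(df) <- c("lineage_annotation", class(df))
  df
}
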