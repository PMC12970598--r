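#' Read a DepMap-style expression CSV
#'
#' Comma-separated matrix with one axis of cell lines and one of genes; the
#' first column holds the row-axis ids. Gene headers in the DepMap dialect
#' `"SYMBOL (ENTREZ_ID)"` are reduced to the symbol (the id is kept in the
#' `"entrez_id"` attribute). Orientation is auto-detected by matching ids
#' against the cell-line pattern (default: the DepMap `ACH-` prefix), or
#' forced with `orientation`. Empty fields and `"NA"` read as missing.
#'
#' @param path CSV file path.
#' @param orientation `"auto"`, `"genes_in_rows"` or `"genes_in_cols"`.
#' @param layer Expression layer tag, `"mrna"` or `"protein"`.
#' @param id_pattern Regular expression identifying cell-line ids.
#' @return An [omics_matrix()] (genes x cell lines).
#' @export
read_expression_csv <- function(path,
                                orientation = c("auto", "genes_in_rows",
                                                "genes_in_cols"),
                                layer = c("mrna", "protein"),
                                id_pattern = "^ACH-") {
  layer <- match.arg(layer)
  vals <- read_matrix_csv(path, match.arg(orientation), id_pattern)
  omics_matrix(vals, layer)
}

#' Read a DepMap-style dependency CSV
#'
#' Same format and conventions as [read_expression_csv()], holding
#' CERES-style knockout scores.
#'
#' @inheritParams read_expression_csv
#' @return A [dependency_matrix()] (genes x cell lines).
#' @export
read_dependency_csv <- function(path,
                                orientation = c("auto", "genes_in_rows",
                                                "genes_in_cols"),
                                id_pattern = "^ACH-") {
  dependency_matrix(read_matrix_csv(path, match.arg(orientation), id_pattern))
}

read_matrix_csv <- function(path, orientation, id_pattern) {
  if (!file.exists(path)) data_error(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_double(),
    readr::col_character()  # first column: row ids
  ), na = c("", "NA"), progress = FALSE)
  if (ncol(df) < 2 || nrow(df) < 1) {
    data_error(sprintf("empty or unparseable matrix: %s", path))
  }
  row_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- row_ids
  if (orientation == "auto") {
    row_hit <- mean(grepl(id_pattern, rownames(m)))
    col_hit <- mean(grepl(id_pattern, colnames(m)))
    if (row_hit == col_hit) {
      data_error(sprintf(
        "cannot auto-detect orientation of %s (cell-line pattern '%s' matches neither axis better); pass `orientation`",
        path, id_pattern))
    }
    orientation <- if (row_hit > col_hit) "genes_in_cols" else "genes_in_rows"
  }
  if (orientation == "genes_in_cols") m <- t(m)
  # DepMap "SYMBOL (ID)" headers: keep the symbol, remember the id
  symbols <- sub("\\s*\\(.*\\)\\s*$", "", rownames(m))
  ids <- ifelse(grepl("\\(.*\\)\\s*$", rownames(m)),
                sub("^.*\\(\\s*([^)]*?)\\s*\\)\\s*$", "\\1", rownames(m)),
                NA_character_)
  if (anyDuplicated(symbols)) {
    warning(sprintf("%s: duplicate gene ids after symbol extraction; keeping first",
                    path))
    keep <- !duplicated(symbols)
    m <- m[keep, , drop = FALSE]
    symbols <- symbols[keep]
    ids <- ids[keep]
  }
  rownames(m) <- symbols
  attr(m, "entrez_id") <- stats::setNames(ids, symbols)
  m
}

#' Write a matrix as a DepMap-style CSV
#'
#' Cell lines in rows, genes in columns (the portal convention); reals at 6
#' significant digits, missing values as empty fields.
#'
#' @param mat An [omics_matrix()] or [dependency_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(mat, path) {
  m <- t(unclass(mat))  # cell lines x genes
  header <- paste(c("cell_line", colnames(m)), collapse = ",")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format_real(m[i, ], na = "")), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cell-line lineage table
#'
#' TSV or CSV (by extension) with columns `cell_line` and `lineage`.
#' Duplicated rows are deduplicated; a cell line mapped to two lineages is
#' an error.
#'
#' @param path File path.
#' @return A [lineage_annotation()].
#' @export
read_lineage_table <- function(path) {
  if (!file.exists(path)) data_error(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  if (nrow(df) == 0) data_error(sprintf("empty lineage table: %s", path))
  if (!all(c("cell_line", "lineage") %in% names(df))) {
    data_error(sprintf("%s: columns 'cell_line' and 'lineage' required", path))
  }
  lineage_annotation(df$cell_line, df$lineage)
}

#' Read gene sets (GMT or one-symbol-per-line)
#'
#' GMT rows are `name<TAB>description<TAB>member...`; plain lists hold one
#' symbol per line and take the set name from the file name. Members are
#' deduplicated; empty sets are dropped with a warning.
#'
#' @param path File path.
#' @param format `"auto"` (GMT for `.gmt` files), `"gmt"` or `"list"`.
#' @return A named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "list")) {
  format <- match.arg(format)
  if (!file.exists(path)) data_error(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "list"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "gmt") {
    sets <- list()
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      members <- unique(f[-(1:2)])
      members <- members[nzchar(members)]
      if (length(f) < 3 || length(members) == 0) {
        warning(sprintf("dropping empty gene set '%s'", f[1]))
        next
      }
      sets[[f[1]]] <- gene_set(f[1], members)
    }
    if (length(sets) == 0) data_error(sprintf("no usable gene sets in %s", path))
    sets
  } else {
    name <- tools::file_path_sans_ext(basename(path))
    members <- unique(trimws(lines))
    if (length(members) == 0) data_error(sprintf("no genes in %s", path))
    stats::setNames(list(gene_set(name, members)), name)
  }
}

ed_table_columns <- c("gene", "context", "layer", "method", "n_obs",
                      "rho", "rho_sd", "z", "p", "fdr", "status")

#' Write an ED table as TSV
#'
#' Stable column order, reals at 6 significant digits, `NA` for missing;
#' identical tables always produce identical bytes. [read_ed_table()] is the
#' paired reader.
#'
#' @param table An ED table from [run_ed_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ed_table <- function(table, path) {
  stopifnot(all(ed_table_columns %in% names(table)))
  tb <- table[, ed_table_columns]
  lines <- paste(tb$gene, tb$context, tb$layer, tb$method, tb$n_obs,
                 format_real(tb$rho), format_real(tb$rho_sd),
                 format_real(tb$z), format_real(tb$p), format_real(tb$fdr),
                 tb$status, sep = "\t")
  writeLines(c(paste(ed_table_columns, collapse = "\t"), lines), path)
  invisible(path)
}

#' Read an ED table written by [write_ed_table()]
#'
#' @param path TSV path.
#' @return A tibble with the ED table columns.
#' @export
read_ed_table <- function(path) {
  if (!file.exists(path)) data_error(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), context = readr::col_character(),
    layer = readr::col_character(), method = readr::col_character(),
    n_obs = readr::col_integer(), rho = readr::col_double(),
    rho_sd = readr::col_double(), z = readr::col_double(),
    p = readr::col_double(), fdr = readr::col_double(),
    status = readr::col_character()), na = "NA", progress = FALSE)
  tibble::as_tibble(df)
}

# 6-significant-digit representation used by every writer; deterministic
format_real <- function(x, na = "NA") {
  out <- ifelse(is.na(x), na, formatC(x, digits = 6, format = "g"))
  out
}
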