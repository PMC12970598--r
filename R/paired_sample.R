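#' Paired expression/dependency sample for one gene
#'
#' Bundles one gene's expression values and CRISPR dependency scores across
#' the same cell lines, applying pairwise-complete filtering: any position
#' where either value is missing is dropped from both vectors. The retained
#' pair count `n` is recorded; downstream fits never see missing values.
#'
#' @param gene_id Identifier for the gene (single string).
#' @param x Numeric vector of expression values (log-scale TPM or normalized
#'   protein abundance); may contain `NA`.
#' @param y Numeric vector of dependency scores (CERES-like: more negative =
#'   stronger dependency), index-aligned to `x`; may contain `NA`.
#'
#' @return An object of class `paired_sample`: a list with elements
#'   `gene_id`, `x`, `y` (complete pairs, original order) and `n`.
#' @examples
#' ps <- paired_sample("TP63", c(1, NA, 3), c(0.1, 0.2, NA))
#' ps$n  # 1
#' @export
paired_sample <- function(gene_id, x, y) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    data_error(sprintf(
      "paired_sample('%s'): x and y must be index-aligned (lengths %d vs %d)",
      gene_id, length(x), length(y)))
  }
  keep <- !is.na(x) & !is.na(y)
  structure(
    list(gene_id = gene_id, x = x[keep], y = y[keep], n = sum(keep)),
    class = "paired_sample"
  )
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample> %s: n = %d complete pairs\n", x$gene_id, x$n))
  invisible(x)
}

# internal: sufficient statistics (n, sum x, sum y, sum x^2, sum y^2, sum xy)
suff_stats <- function(x, y) {
  c(length(x), sum(x), sum(y), sum(x * x), sum(y * y), sum(x * y))
}

# internal: center and scale both margins; correlation is invariant to this
# and it makes the priors scale-free. Returns NULL if either margin is
# constant (zero variance).
standardize_pair <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NULL)
  list(x = (x - mean(x)) / sx, y = (y - mean(y)) / sy)
}
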