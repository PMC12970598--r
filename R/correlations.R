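#' Pearson correlation of a paired sample
#'
#' Standard product-moment correlation, the frequentist comparator used in
#' the simulation benchmark and the comparator screens.
#'
#' @param sample A [paired_sample()] with `n >= 3`.
#' @return The correlation, or `NA` when either margin is constant
#'   (degenerate input).
#' @export
pearson_correlation <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  if (sample$n < 3) data_error("pearson_correlation requires n >= 3")
  if (stats::sd(sample$x) == 0 || stats::sd(sample$y) == 0) return(NA_real_)
  stats::cor(sample$x, sample$y)
}

#' Spearman rank correlation of a paired sample
#'
#' Pearson correlation of average-ranked data (ties receive average ranks).
#'
#' @inheritParams pearson_correlation
#' @return The rank correlation, or `NA` for constant input.
#' @export
spearman_correlation <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  if (sample$n < 3) data_error("spearman_correlation requires n >= 3")
  rx <- rank(sample$x, ties.method = "average")
  ry <- rank(sample$y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# internal: t-transform p-value for a (rank) correlation coefficient, used to
# give the comparator screens p-values on the same footing
cor_t_pvalue <- function(r, n) {
  r <- unname(r)
  n <- unname(n)
  if (!is.finite(r) || n < 3) return(c(stat = NA_real_, p = NA_real_))
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) return(c(stat = sign(r) * Inf, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  c(stat = t, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, capped at 1.
#' Missing entries are passed through as `NA` and excluded from the number
#' of tests `m`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted values in input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    data_error("bh_fdr: p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}
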