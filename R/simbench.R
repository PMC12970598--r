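#' Simulate one contaminated bivariate sample
#'
#' Draws `n` points from a standard bivariate Gaussian with correlation
#' `true_rho`; each point is then independently replaced, with probability
#' `noise_fraction`, by a draw from an uncorrelated bivariate Gaussian with
#' SD `outlier_sd_multiplier` -- the outlier model of the estimator
#' benchmark. Uses the current R RNG stream, so wrap in `set.seed()` for
#' reproducibility.
#'
#' @param true_rho Correlation of the clean component, in `[-1, 1]`.
#' @param n Sample size.
#' @param noise_fraction Probability that a point is an outlier, in `[0, 1]`.
#' @param outlier_sd_multiplier SD of the outlier component (default 5).
#' @param gene_id Identifier for the resulting sample.
#' @return A [paired_sample()].
#' @export
simulate_pair <- function(true_rho, n, noise_fraction = 0,
                          outlier_sd_multiplier = 5, gene_id = "sim") {
  stopifnot(true_rho >= -1, true_rho <= 1, n >= 1,
            noise_fraction >= 0, noise_fraction <= 1,
            outlier_sd_multiplier > 0)
  x <- stats::rnorm(n)
  y <- true_rho * x + sqrt(1 - true_rho^2) * stats::rnorm(n)
  out <- stats::runif(n) < noise_fraction
  n_out <- sum(out)
  if (n_out > 0) {
    x[out] <- outlier_sd_multiplier * stats::rnorm(n_out)
    y[out] <- outlier_sd_multiplier * stats::rnorm(n_out)
  }
  paired_sample(gene_id, x, y)
}

#' The benchmark scenario grid
#'
#' The full factorial grid of the estimator benchmark: true correlation from
#' -1 to 1 in steps of 0.25 (9 values), sample sizes
#' `{5, 7, 10, 20, 30, 60, 100}`, and outlier fractions
#' `{0.1, 0.3, 0.5, 0.8, 1}` -- 315 scenarios. Each scenario carries a seed
#' derived from `seed` and its grid position, so partial grids reproduce the
#' corresponding full-grid cells.
#'
#' @param n_replicates Replicates per scenario (default 100).
#' @param seed Base seed.
#' @param rho_values,n_values,noise_fractions Optional axis overrides.
#' @param outlier_sd_multiplier Outlier SD (default 5).
#' @return A tibble of scenarios with columns `scenario_index`, `true_rho`,
#'   `n`, `noise_fraction`, `n_replicates`, `outlier_sd_multiplier`,
#'   `scenario_seed`.
#' @export
default_grid <- function(n_replicates = 100, seed = 1,
                         rho_values = seq(-1, 1, by = 0.25),
                         n_values = c(5, 7, 10, 20, 30, 60, 100),
                         noise_fractions = c(0.1, 0.3, 0.5, 0.8, 1),
                         outlier_sd_multiplier = 5) {
  g <- expand.grid(true_rho = rho_values, n = n_values,
                   noise_fraction = noise_fractions,
                   KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    scenario_index = seq_len(nrow(g)),
    true_rho = g$true_rho,
    n = as.integer(g$n),
    noise_fraction = g$noise_fraction,
    n_replicates = as.integer(n_replicates),
    outlier_sd_multiplier = outlier_sd_multiplier,
    scenario_seed = (as.numeric(seed) + 7919 * seq_len(nrow(g))) %% 2147483629
  )
}

# deterministic per-replicate seed from a scenario seed
replicate_seed <- function(scenario_seed, replicate) {
  (as.numeric(scenario_seed) + 104729 * replicate) %% 2147483629
}

#' Run the estimator benchmark over a scenario grid
#'
#' For every scenario and replicate, simulates a contaminated sample and
#' estimates the correlation with each requested method (`"bayesian"` uses
#' the posterior mean of `rho`). Per scenario and method, reports the mean
#' estimate, bias, variance and mean squared error (population moments, so
#' `mse = bias^2 + variance` holds exactly); replicates where an estimator
#' is undefined (constant data) are excluded from the moments and counted
#' in `n_failed`.
#'
#' @param grid A scenario tibble from [default_grid()] (possibly subset).
#' @param methods Subset of `c("bayesian", "pearson", "spearman")`.
#' @param prior,config Bayesian model settings (the per-fit seeds come from
#'   the scenario seeds, not `config$seed`).
#' @return A long tibble: one row per scenario x method with columns
#'   `scenario_index`, `true_rho`, `n`, `noise_fraction`, `method`, `n_ok`,
#'   `n_failed`, `mean_estimate`, `bias`, `variance`, `mse`.
#' @export
run_benchmark <- function(grid,
                          methods = c("bayesian", "pearson", "spearman"),
                          prior = prior_spec(), config = mcmc_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(nrow(grid) >= 1)
  pc <- prior_codes(prior)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- grid[i, ]
    R <- sc$n_replicates
    est <- matrix(NA_real_, nrow = R, ncol = length(methods),
                  dimnames = list(NULL, methods))
    suff <- matrix(NA_real_, nrow = R, ncol = 6)
    r_emp <- rep(NA_real_, R)
    for (r in seq_len(R)) {
      set.seed(replicate_seed(sc$scenario_seed, r))
      ps <- simulate_pair(sc$true_rho, sc$n, sc$noise_fraction,
                          sc$outlier_sd_multiplier)
      sdx <- stats::sd(ps$x); sdy <- stats::sd(ps$y)
      if (sdx > 0 && sdy > 0) r_emp[r] <- stats::cor(ps$x, ps$y)
      if ("pearson" %in% methods) est[r, "pearson"] <- r_emp[r]
      if ("spearman" %in% methods) {
        rx <- rank(ps$x); ry <- rank(ps$y)
        est[r, "spearman"] <- if (stats::sd(rx) > 0 && stats::sd(ry) > 0)
          stats::cor(rx, ry) else NA_real_
      }
      if (!is.na(r_emp[r])) {
        suff[r, ] <- c(ps$n, 0, 0, ps$n - 1, ps$n - 1, (ps$n - 1) * r_emp[r])
      }
    }
    if ("bayesian" %in% methods) {
      fit_ok <- which(!is.na(r_emp))
      if (length(fit_ok) > 0) {
        seeds <- replicate_seed(sc$scenario_seed, fit_ok + 500000)
        fits <- cpp_fit_batch(suff[fit_ok, , drop = FALSE], seeds,
                              prior$mu_scale, prior$sigma_scale,
                              pc$rho_code, pc$shrink_k,
                              config$n_chains, config$n_iter, config$n_burnin,
                              config$thin, config$adapt, config$target_accept)
        est[fit_ok, "bayesian"] <- fits[, "rho_mean"]
      }
    }
    out[[i]] <- dplyr::bind_rows(lapply(methods, function(m) {
      e <- est[, m]
      ok <- e[!is.na(e)]
      mu <- mean(ok)
      tibble::tibble(scenario_index = sc$scenario_index,
                     true_rho = sc$true_rho, n = sc$n,
                     noise_fraction = sc$noise_fraction, method = m,
                     n_ok = length(ok), n_failed = sum(is.na(e)),
                     mean_estimate = mu,
                     bias = mu - sc$true_rho,
                     variance = mean((ok - mu)^2),
                     mse = mean((ok - sc$true_rho)^2))
    }))
  }
  dplyr::bind_rows(out)
}

#' Empirical type-I error rate of the posterior z test
#'
#' Simulates independent null genes (`rho = 0`), fits each with the Bayesian
#' model, and reports the fraction with `p < alpha`. A calibrated test at
#' `alpha = 0.05` should reject roughly 5% of null genes.
#'
#' @param n Sample size per gene.
#' @param alpha Nominal level.
#' @param n_replicates Number of null genes.
#' @param prior,config Model settings.
#' @param seed Seed for data generation and fits.
#' @return A list with `rate`, `p_values` and the per-gene `rho_mean`.
#' @export
type1_error_rate <- function(n = 30, alpha = 0.05, n_replicates = 1000,
                             prior = prior_spec(), config = mcmc_config(),
                             seed = 1) {
  stopifnot(n >= config$min_pairs, alpha >= 0, alpha <= 1)
  set.seed(seed)
  suff <- matrix(NA_real_, nrow = n_replicates, ncol = 6)
  for (r in seq_len(n_replicates)) {
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    suff[r, ] <- c(n, 0, 0, n - 1, n - 1, (n - 1) * stats::cor(x, y))
  }
  pc <- prior_codes(prior)
  seeds <- (as.numeric(seed) + 7 + 131 * seq_len(n_replicates)) %% 2147483629
  fits <- cpp_fit_batch(suff, seeds,
                        prior$mu_scale, prior$sigma_scale,
                        pc$rho_code, pc$shrink_k,
                        config$n_chains, config$n_iter, config$n_burnin,
                        config$thin, config$adapt, config$target_accept)
  z <- fits[, "rho_mean"] / fits[, "rho_sd"]
  p <- 2 * stats::pnorm(-abs(z))
  list(rate = mean(p < alpha), p_values = p, rho_mean = fits[, "rho_mean"])
}
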