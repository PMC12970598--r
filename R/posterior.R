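#' Log posterior density of the bivariate-Gaussian correlation model
#'
#' Evaluates the log prior plus the log bivariate-Gaussian likelihood of the
#' sample at the given parameter values, on the natural parameter scale
#' (means, standard deviations, correlation). All prior normalizing
#' constants are included, so two parameter settings can be compared as
#' genuine posterior density ratios. The data are used exactly as supplied;
#' [fit_bayesian_correlation()] standardizes its input before targeting this
#' same density.
#'
#' @param params A [model_params()] object.
#' @param sample A [paired_sample()] with `n >= 2`.
#' @param prior A [prior_spec()].
#' @return The log posterior density (a single finite number for interior
#'   parameter values; `-Inf` only at `|rho| = 1` with off-line data).
#' @export
log_posterior <- function(params, sample, prior = prior_spec()) {
  stopifnot(inherits(params, "model_params"),
            inherits(sample, "paired_sample"),
            inherits(prior, "prior_spec"))
  if (sample$n < 2) {
    data_error("log_posterior requires at least 2 complete pairs")
  }
  x <- sample$x
  y <- sample$y
  mu1 <- params$mu1; mu2 <- params$mu2
  s1 <- params$sigma1; s2 <- params$sigma2
  rho <- params$rho
  om <- 1 - rho^2
  zx <- (x - mu1) / s1
  zy <- (y - mu2) / s2
  if (om <= 0) {
    # degenerate ridge: density is +Inf on the line, -Inf off it; report -Inf
    # unless every standardized pair sits exactly on the ridge
    on_ridge <- all(zx == sign(rho) * zy)
    return(if (on_ridge) Inf else -Inf)
  }
  n <- sample$n
  ll <- -n * log(2 * pi) - n * (log(s1) + log(s2)) - n / 2 * log(om) -
    sum(zx^2 - 2 * rho * zx * zy + zy^2) / (2 * om)
  lp <- stats::dnorm(mu1, 0, prior$mu_scale, log = TRUE) +
    stats::dnorm(mu2, 0, prior$mu_scale, log = TRUE) +
    log_half_cauchy(s1, prior$sigma_scale) +
    log_half_cauchy(s2, prior$sigma_scale) +
    log_rho_prior(rho, prior)
  ll + lp
}

log_half_cauchy <- function(s, scale) {
  log(2 / (pi * scale)) - log1p((s / scale)^2)
}

log_rho_prior <- function(rho, prior) {
  if (prior$rho_prior == "uniform") {
    prior$rho_log_norm
  } else {
    prior$shrink_strength * log1p(-rho^2) + prior$rho_log_norm
  }
}

#' Fit the Bayesian correlation of a paired sample by MCMC
#'
#' Standardizes both margins (the correlation is invariant to this and it
#' makes the priors scale-free), then runs `n_chains` adaptive random-walk
#' Metropolis chains on the transformed parameters
#' `(mu1, mu2, log sigma1, log sigma2, atanh rho)` and summarizes the pooled
#' post-burn-in draws of `rho`. The posterior mean and SD are the screen's
#' `rho` estimate and its uncertainty; their ratio is the test statistic used
#' by [z_statistic()]. Results are deterministic given (data, prior, config,
#' seed).
#'
#' @param sample A [paired_sample()].
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param keep_draws If `TRUE`, the retained draws (matrix: iterations x
#'   chains) are attached as `$draws`.
#' @return An object of class `posterior_summary` with fields `rho_mean`,
#'   `rho_sd`, `rho_median`, `ci` (95% credible interval), `rhat`, `ess`,
#'   `accept_rate`, `n_obs`, `converged`, and `status` (one of `"ok"`,
#'   `"low_n"`, `"constant_input"`, `"not_converged"`). For non-`"ok"`
#'   statuses other than `"not_converged"` the numeric summaries are `NA`.
#' @examples
#' set.seed(1)
#' ps <- paired_sample("g", rnorm(40), rnorm(40))
#' fit <- fit_bayesian_correlation(ps, config = mcmc_config(seed = 7))
#' fit$rho_mean
#' @export
fit_bayesian_correlation <- function(sample, prior = prior_spec(),
                                     config = mcmc_config(),
                                     keep_draws = FALSE) {
  stopifnot(inherits(sample, "paired_sample"),
            inherits(prior, "prior_spec"),
            inherits(config, "mcmc_config"))
  if (sample$n < config$min_pairs) {
    return(empty_posterior_summary(sample$n, "low_n"))
  }
  sx <- stats::sd(sample$x)
  sy <- stats::sd(sample$y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    return(empty_posterior_summary(sample$n, "constant_input"))
  }
  # sufficient statistics of the standardized data in closed form; the
  # screen's batch path builds the identical statistics, so single fits and
  # screen rows coincide exactly at the same seed
  n <- sample$n
  r <- stats::cor(sample$x, sample$y)
  suff <- c(n, 0, 0, n - 1, n - 1, (n - 1) * r)
  pc <- prior_codes(prior)
  draws <- cpp_sample_rho(suff, config$seed,
                          prior$mu_scale, prior$sigma_scale,
                          pc$rho_code, pc$shrink_k,
                          config$n_chains, config$n_iter, config$n_burnin,
                          config$thin, config$adapt, config$target_accept)
  s <- cpp_summarize_draws(draws)
  converged <- is.finite(s[["rhat"]]) && is.finite(s[["ess"]]) &&
    s[["rhat"]] < config$rhat_threshold && s[["ess"]] >= config$ess_threshold
  out <- structure(
    list(rho_mean = s[["rho_mean"]], rho_sd = s[["rho_sd"]],
         rho_median = s[["rho_median"]],
         ci = c(lower = s[["ci_lo"]], upper = s[["ci_hi"]]),
         rhat = s[["rhat"]], ess = s[["ess"]],
         accept_rate = NA_real_,
         n_obs = sample$n, converged = converged,
         status = if (converged) "ok" else "not_converged"),
    class = "posterior_summary")
  if (keep_draws) out$draws <- draws
  out
}

empty_posterior_summary <- function(n_obs, status) {
  structure(
    list(rho_mean = NA_real_, rho_sd = NA_real_, rho_median = NA_real_,
         ci = c(lower = NA_real_, upper = NA_real_),
         rhat = NA_real_, ess = NA_real_, accept_rate = NA_real_,
         n_obs = n_obs, converged = FALSE, status = status),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary>\n")
  if (x$status %in% c("low_n", "constant_input")) {
    cat(sprintf("  status: %s (n_obs = %d)\n", x$status, x$n_obs))
  } else {
    cat(sprintf("  rho: %.3f (sd %.3f, median %.3f, 95%% CI [%.3f, %.3f])\n",
                x$rho_mean, x$rho_sd, x$rho_median, x$ci[1], x$ci[2]))
    cat(sprintf("  n_obs: %d  rhat: %.3f  ess: %.0f  converged: %s\n",
                x$n_obs, x$rhat, x$ess, x$converged))
  }
  invisible(x)
}

#' Posterior z statistic of the correlation
#'
#' The deviation of the posterior mean of `rho` from its null value (zero)
#' in units of the posterior SD: `z = rho_mean / rho_sd`.
#'
#' @param summary A `posterior_summary` from [fit_bayesian_correlation()].
#' @return The z statistic (single number).
#' @export
z_statistic <- function(summary) {
  stopifnot(inherits(summary, "posterior_summary"))
  if (!is.finite(summary$rho_sd) || summary$rho_sd <= 0) {
    data_error("z_statistic: degenerate posterior (rho_sd not positive)")
  }
  summary$rho_mean / summary$rho_sd
}

#' Two-sided p-value of a standard-normal z statistic
#'
#' @param z Finite numeric vector of z statistics.
#' @return `2 * (1 - Phi(|z|))`, elementwise.
#' @export
p_value_from_z <- function(z) {
  if (any(!is.finite(z))) data_error("p_value_from_z: non-finite z")
  2 * stats::pnorm(-abs(z))
}

#' Grid-quadrature posterior summary of rho
#'
#' Reference implementation of the rho posterior by dense numerical
#' integration, sharing the model of [log_posterior()] but none of the
#' sampling machinery. The Gaussian integral over `(mu1, mu2)` is evaluated
#' in closed form (the likelihood is quadratic in the means and their prior
#' is normal), and `(log sigma1, log sigma2, rho)` are integrated on a dense
#' grid. The analytic mean integral matters: near `|rho| = 1` the
#' conditional posterior of the means collapses onto a ridge that no fixed
#' grid resolves. Intended for validating the MCMC sampler on small samples.
#'
#' @param sample A [paired_sample()] with non-constant margins.
#' @param prior A [prior_spec()].
#' @param standardize Standardize margins first (matching the fit)? Default
#'   `TRUE`.
#' @param n_logsigma,n_rho Grid sizes for the log-SD and rho dimensions.
#' @param logsigma_half Half-width of the log-SD grid (centered on 0, the
#'   posterior center for standardized data).
#' @return A list with `rho_mean`, `rho_sd`, and the marginal grid
#'   (`rho`, `weight`).
#' @export
rho_posterior_quadrature <- function(sample, prior = prior_spec(),
                                     standardize = TRUE,
                                     n_logsigma = 61, n_rho = 1201,
                                     logsigma_half = 3) {
  stopifnot(inherits(sample, "paired_sample"), sample$n >= 2)
  x <- sample$x
  y <- sample$y
  if (standardize) {
    std <- standardize_pair(x, y)
    if (is.null(std)) data_error("quadrature requires non-constant margins")
    x <- std$x
    y <- std$y
  }
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  cxx <- sum((x - xbar)^2)
  cyy <- sum((y - ybar)^2)
  cxy <- sum((x - xbar) * (y - ybar))
  tau2 <- prior$mu_scale^2

  ls_grid <- seq(-logsigma_half, logsigma_half, length.out = n_logsigma)
  # open rho grid: cell midpoints, avoiding the +-1 boundary
  rho_grid <- seq(-1 + 1 / n_rho, 1 - 1 / n_rho, length.out = n_rho)

  g <- expand.grid(ls1 = ls_grid, ls2 = ls_grid)
  s1 <- exp(g$ls1); s2 <- exp(g$ls2)
  # theta-independent log pieces: half-Cauchy priors with the sigma
  # Jacobian, and the data-independent likelihood normalization
  lp_base <- -log1p((s1 / prior$sigma_scale)^2) -
    log1p((s2 / prior$sigma_scale)^2) + g$ls1 + g$ls2 -
    n * (log(2 * pi) + g$ls1 + g$ls2)

  k_shrink <- if (prior$rho_prior == "shrink") prior$shrink_strength else 0
  log_w <- numeric(n_rho)
  for (i in seq_len(n_rho)) {
    rho <- rho_grid[i]
    om <- 1 - rho^2
    # centered likelihood exponent
    quad <- (cxx / s1^2 - 2 * rho * cxy / (s1 * s2) + cyy / s2^2) / (2 * om)
    # closed-form integral over (mu1, mu2): precision M = A + I/tau2 with
    # A = (n/om) [1/s1^2, -rho/(s1 s2); -rho/(s1 s2), 1/s2^2]; the
    # likelihood is centered at (xbar, ybar), the prior at 0
    a11 <- n / (om * s1^2) + 1 / tau2
    a22 <- n / (om * s2^2) + 1 / tau2
    a12 <- -n * rho / (om * s1 * s2)
    detM <- a11 * a22 - a12^2
    m0sq <- xbar^2 + ybar^2
    # exp(-m0' m0 / (2 tau2)) * exp(h' Minv h / 2), h = m0 / tau2
    hMh <- (a22 * xbar^2 - 2 * a12 * xbar * ybar + a11 * ybar^2) /
      (detM * tau2^2)
    log_mu_int <- -0.5 * log(detM) - log(tau2) - 0.5 * m0sq / tau2 + 0.5 * hMh
    lp <- lp_base - n / 2 * log(om) - quad + log_mu_int + k_shrink * log(om)
    m <- max(lp)
    log_w[i] <- m + log(sum(exp(lp - m)))
  }
  weight <- exp(log_w - max(log_w))
  weight <- weight / sum(weight)
  mu <- sum(weight * rho_grid)
  v <- sum(weight * (rho_grid - mu)^2)
  list(rho_mean = mu, rho_sd = sqrt(v),
       marginal = tibble::tibble(rho = rho_grid, weight = weight))
}
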