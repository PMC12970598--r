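#' Bivariate-Gaussian model parameters
#'
#' Container for the five parameters of the bivariate Gaussian used to model
#' one gene's (expression, dependency) pairs. `rho` is the correlation the
#' whole screen reports.
#'
#' @param mu1,mu2 Means of the two margins.
#' @param sigma1,sigma2 Standard deviations; strictly positive.
#' @param rho Correlation in `[-1, 1]`.
#' @return An object of class `model_params`.
#' @export
model_params <- function(mu1, mu2, sigma1, sigma2, rho) {
  stopifnot(is.finite(mu1), is.finite(mu2),
            is.finite(sigma1), sigma1 > 0,
            is.finite(sigma2), sigma2 > 0,
            is.finite(rho), rho >= -1, rho <= 1)
  structure(list(mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
                 rho = rho),
            class = "model_params")
}

#' Prior specification for the Bayesian correlation model
#'
#' Priors are placed on the standardized scale (each margin centered and
#' scaled before fitting), so the defaults are scale-free: weakly
#' informative normals on the means and heavy-tailed half-Cauchy priors on
#' the standard deviations, which tolerate the occasional outlying cell line
#' without letting it dominate the fit. The correlation prior is uniform on
#' `(-1, 1)` by default; an optional shrinkage prior proportional to
#' `(1 - rho^2)^k` pulls small-sample estimates toward zero.
#'
#' @param mu_scale Prior SD of the margin means (standardized scale).
#' @param sigma_scale Scale of the half-Cauchy prior on the margin SDs.
#' @param rho_prior `"uniform"` or `"shrink"`.
#' @param shrink_strength Exponent `k >= 0` of the shrinkage prior; ignored
#'   for `rho_prior = "uniform"`.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec()                          # defaults
#' prior_spec(rho_prior = "shrink", shrink_strength = 1)
#' @export
prior_spec <- function(mu_scale = 10, sigma_scale = 2.5,
                       rho_prior = c("uniform", "shrink"),
                       shrink_strength = 1) {
  rho_prior <- match.arg(rho_prior)
  stopifnot(is.finite(mu_scale), mu_scale > 0,
            is.finite(sigma_scale), sigma_scale > 0,
            is.finite(shrink_strength), shrink_strength >= 0)
  log_norm <- if (rho_prior == "uniform") {
    log(0.5)
  } else {
    k <- shrink_strength
    # integral of (1 - r^2)^k over (-1, 1) = 2^(2k+1) * Beta(k+1, k+1)
    lz <- (2 * k + 1) * log(2) + lbeta(k + 1, k + 1)
    # numeric sanity check that the density integrates to one
    chk <- stats::integrate(function(r) exp(k * log1p(-r^2) - lz), -1, 1)
    if (abs(chk$value - 1) > 1e-6) {
      stop("shrinkage prior normalization failed to validate numerically")
    }
    -lz
  }
  structure(list(mu_scale = mu_scale, sigma_scale = sigma_scale,
                 rho_prior = rho_prior, shrink_strength = shrink_strength,
                 rho_log_norm = log_norm),
            class = "prior_spec")
}

#' MCMC sampler configuration
#'
#' Settings for the adaptive random-walk Metropolis sampler. `n_iter` counts
#' post-burn-in iterations per chain; every `thin`-th is retained, and the
#' configuration must retain at least 400 draws in total. Chain `c` is seeded
#' with `seed + c`, so runs are reproducible and chain count changes results
#' predictably.
#'
#' @param n_chains Number of chains.
#' @param n_iter Post-burn-in iterations per chain.
#' @param n_burnin Burn-in iterations per chain (step size adapts here only).
#' @param thin Thinning interval.
#' @param seed Integer seed.
#' @param adapt Adapt the proposal step size during burn-in
#'   (Robbins--Monro toward `target_accept`)?
#' @param target_accept Target acceptance rate of the joint proposal.
#' @param rhat_threshold,ess_threshold Convergence is declared when split
#'   R-hat is below `rhat_threshold` and the effective sample size is at
#'   least `ess_threshold`.
#' @param min_pairs Minimum complete pairs required for a fit; smaller
#'   samples are flagged `low_n` rather than fitted.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_iter = 2000, n_burnin = 1000,
                        thin = 1, seed = 1, adapt = TRUE,
                        target_accept = 0.3,
                        rhat_threshold = 1.1, ess_threshold = 200,
                        min_pairs = 5) {
  stopifnot(n_chains >= 1, n_iter >= 1, n_burnin >= 0, thin >= 1,
            target_accept > 0, target_accept < 1,
            rhat_threshold > 1, ess_threshold > 0, min_pairs >= 2)
  retained <- (n_iter %/% thin) * n_chains
  if (retained < 400) {
    usage_error(sprintf(
      "mcmc_config retains only %d draws (n_iter * n_chains / thin); at least 400 required",
      retained))
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt = isTRUE(adapt),
                 target_accept = target_accept,
                 rhat_threshold = rhat_threshold,
                 ess_threshold = ess_threshold,
                 min_pairs = as.integer(min_pairs)),
            class = "mcmc_config")
}

# internal: prior pieces for the C++ sampler
prior_codes <- function(prior) {
  list(rho_code = if (prior$rho_prior == "shrink") 1L else 0L,
       shrink_k = prior$shrink_strength)
}
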