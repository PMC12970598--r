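# Independent reference implementations used to validate package routines.

# Benjamini-Hochberg by literal step-up over sorted p-values.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sided Fisher p by explicit hypergeometric enumeration with log-choose
# arithmetic (no dhyper), minimum-likelihood rule.
brute_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d
  m <- a + c
  k <- a + b
  lo <- max(0, k - (b + d))
  hi <- min(k, m)
  supp <- lo:hi
  dens <- exp(lchoose(m, supp) + lchoose(N - m, k - supp) - lchoose(N, k))
  min(1, sum(dens[dens <= dens[supp == a] * (1 + 1e-7)]))
}

# Full bivariate-normal log density evaluated through matrix algebra,
# independent of the closed-form expression in the package.
brute_bvn_loglik <- function(x, y, mu1, mu2, s1, s2, rho) {
  S <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2)
  Si <- solve(S)
  ld <- determinant(S, logarithm = TRUE)$modulus
  pts <- rbind(x - mu1, y - mu2)
  q <- colSums(pts * (Si %*% pts))
  sum(-log(2 * pi) - 0.5 * ld - 0.5 * q)
}

# a small sample with an exactly prescribed sample correlation
sample_with_cor <- function(r, n, gene_id = "g") {
  x <- as.numeric(scale(stats::rnorm(n)))
  e <- as.numeric(scale(stats::resid(stats::lm(stats::rnorm(n) ~ x))))
  paired_sample(gene_id, x, r * x + sqrt(1 - r^2) * e)
}

# light MCMC settings for unit tests (retains 2000 draws)
light_config <- function(seed = 1, ...) {
  mcmc_config(n_chains = 2, n_iter = 1000, n_burnin = 500, seed = seed, ...)
}

# small synthetic screen fixture shared by screen/cli tests
small_fixture <- function(seed = 1, n_genes = 60, n_planted_pan = 6) {
  generate_synthetic_depmap(n_lineages = 3, lines_per_lineage = 10,
                            n_genes = n_genes,
                            n_planted_pan = n_planted_pan,
                            n_planted_lineage = 2, seed = seed)
}
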