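// Adaptive random-walk Metropolis sampler for the correlation of a bivariate
// Gaussian. The two means are integrated out analytically and the chain runs
// on (log sigma1, log sigma2, atanh rho). The likelihood is evaluated from
// sufficient statistics so the per-iteration cost does not grow with the
// number of observations, which is what makes genome-wide screens (~2e4
// genes) and calibration studies (1e5 fits) tractable on one core.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093454836;

// ---------------------------------------------------------------------------
// Self-contained RNG (PCG32 + Box-Muller). Using our own stream keeps every
// fit deterministic given its integer seed, independent of R's global RNG
// state and of how many fits ran before it.
// ---------------------------------------------------------------------------
struct Pcg32 {
  uint64_t state;
  uint64_t inc;
  bool have_spare;
  double spare;

  Pcg32(uint64_t seed, uint64_t seq) : state(0u), have_spare(false), spare(0.0) {
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((32u - rot) & 31u));
  }
  // uniform on (0, 1), never exactly 0 or 1
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.2831853071795864769 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// Sufficient statistics of a paired sample.
struct Suff {
  double n, sx, sy, sxx, syy, sxy;
};

// Centered statistics derived from Suff: everything the mean-marginalized
// target needs.
struct CSuff {
  double n, xbar, ybar, cxx, cyy, cxy;
};

static CSuff center_suff(const Suff& s) {
  CSuff c;
  c.n = s.n;
  c.xbar = s.sx / s.n;
  c.ybar = s.sy / s.n;
  c.cxx = s.sxx - s.n * c.xbar * c.xbar;
  c.cyy = s.syy - s.n * c.ybar * c.ybar;
  c.cxy = s.sxy - s.n * c.xbar * c.ybar;
  if (c.cxx < 0.0) c.cxx = 0.0;
  if (c.cyy < 0.0) c.cyy = 0.0;
  return c;
}

struct Prior {
  double mu_scale;     // normal SD on mu1, mu2
  double sigma_scale;  // half-Cauchy scale on sigma1, sigma2
  int rho_code;        // 0 = uniform on (-1,1), 1 = shrinkage (1-rho^2)^k
  double shrink_k;
};

// Log posterior density on the sampling scale theta = (ls1, ls2, z),
// z = atanh(rho), with the two means integrated out in closed form (the
// likelihood is quadratic in the means and their prior is normal, so the
// mean integral is Gaussian). The rho posterior is identical to the full
// five-parameter model's; sampling the 3-D marginal avoids the mean ridge
// that chokes mixing near |rho| = 1. Includes the Jacobians of
// sigma = exp(ls) and rho = tanh(z); theta-independent constants dropped.
static double log_target(const double* th, const CSuff& s, const Prior& pr) {
  double ls1 = th[0], ls2 = th[1], z = th[2];
  double az = std::fabs(z);
  double u = std::exp(-2.0 * az);                  // in (0, 1]
  double log_om = std::log(4.0) - 2.0 * az - 2.0 * std::log1p(u); // log(1-rho^2)
  double om = std::exp(log_om);
  double rho = (1.0 - u) / (1.0 + u);
  if (z < 0.0) rho = -rho;
  double s1 = std::exp(ls1), s2 = std::exp(ls2);
  double n = s.n;
  double tau2 = pr.mu_scale * pr.mu_scale;

  double quad = s.cxx / (s1 * s1) - 2.0 * rho * s.cxy / (s1 * s2)
                + s.cyy / (s2 * s2);
  if (quad < 0.0) quad = 0.0; // rounding guard on near-degenerate data

  // Gaussian mean integral: precision M = A + I/tau2 with
  // A = (n/om) [1/s1^2, -rho/(s1 s2); -rho/(s1 s2), 1/s2^2];
  // the likelihood centers the means at (xbar, ybar), the prior at 0.
  double a11 = n / (om * s1 * s1) + 1.0 / tau2;
  double a22 = n / (om * s2 * s2) + 1.0 / tau2;
  double a12 = -n * rho / (om * s1 * s2);
  double detM = a11 * a22 - a12 * a12;
  double hMh = (a22 * s.xbar * s.xbar - 2.0 * a12 * s.xbar * s.ybar
                + a11 * s.ybar * s.ybar) / (detM * tau2 * tau2);
  double log_mu_int = -0.5 * std::log(detM) -
    0.5 * (s.xbar * s.xbar + s.ybar * s.ybar) / tau2 + 0.5 * hMh;

  double ll = -n * (ls1 + ls2) - 0.5 * n * log_om - 0.5 * quad / om
              + log_mu_int;

  // priors (unnormalized) + Jacobians
  double r1 = s1 / pr.sigma_scale, r2 = s2 / pr.sigma_scale;
  double lp = -std::log1p(r1 * r1) + ls1;  // half-Cauchy, d sigma/d ls = sigma
  lp += -std::log1p(r2 * r2) + ls2;
  lp += log_om;                            // d rho/d z = 1 - rho^2
  if (pr.rho_code == 1) lp += pr.shrink_k * log_om;

  double out = ll + lp;
  if (!std::isfinite(out)) out = -std::numeric_limits<double>::infinity();
  return out;
}

// Run one chain; writes `n_keep` retained rho draws into out[0..n_keep-1].
// Returns the acceptance rate over post-burn-in iterations.
static double run_chain(const CSuff& s, const Prior& pr, uint64_t seed,
                        int n_burnin, int n_iter, int thin, bool adapt,
                        double target_accept, double* out) {
  Pcg32 rng(seed, 0x853c49e6748fea9bULL);

  // method-of-moments starting values with chain-specific jitter
  double n = s.n;
  double vx = std::max(s.cxx / n, 1e-10);
  double vy = std::max(s.cyy / n, 1e-10);
  double r = s.cxy / n / std::sqrt(vx * vy);
  if (r > 0.95) r = 0.95;
  if (r < -0.95) r = -0.95;

  double base[3] = {1.0 / std::sqrt(2.0 * n), 1.0 / std::sqrt(2.0 * n),
                    1.0 / std::sqrt(std::max(n - 3.0, 1.0))};
  double th[3] = {0.5 * std::log(vx), 0.5 * std::log(vy), std::atanh(r)};
  for (int j = 0; j < 3; ++j) th[j] += 2.0 * base[j] * rng.norm();

  double lf = std::log(2.38 / std::sqrt(3.0)); // global log step-size factor
  double lp_cur = log_target(th, s, pr);

  // burn-in covariance adaptation (Welford running moments); the proposal
  // switches from the diagonal base scales to the Cholesky factor of the
  // empirical posterior covariance once enough burn-in history exists,
  // which decorrelates the (log sigma, atanh rho) coupling that appears
  // at strong correlations
  double wm[3] = {0, 0, 0};
  double ws[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  long wn = 0;
  double L[9];
  bool use_L = false;

  int total = n_burnin + n_iter;
  int kept = 0, acc_post = 0;
  double prop[3], eps[3];
  for (int t = 1; t <= total; ++t) {
    double f = std::exp(lf);
    for (int j = 0; j < 3; ++j) eps[j] = rng.norm();
    if (use_L) {
      prop[0] = th[0] + f * L[0] * eps[0];
      prop[1] = th[1] + f * (L[3] * eps[0] + L[4] * eps[1]);
      prop[2] = th[2] + f * (L[6] * eps[0] + L[7] * eps[1] + L[8] * eps[2]);
    } else {
      for (int j = 0; j < 3; ++j) prop[j] = th[j] + f * base[j] * eps[j];
    }
    double lp_prop = log_target(prop, s, pr);
    double alpha = std::exp(std::min(0.0, lp_prop - lp_cur));
    bool accepted = rng.unif() < alpha;
    if (accepted) {
      std::copy(prop, prop + 3, th);
      lp_cur = lp_prop;
    }
    if (t <= n_burnin) {
      if (adapt) {
        lf += std::pow((double)t, -0.6) * (alpha - target_accept);
        ++wn;
        double d0 = th[0] - wm[0], d1 = th[1] - wm[1], d2 = th[2] - wm[2];
        wm[0] += d0 / wn; wm[1] += d1 / wn; wm[2] += d2 / wn;
        double e0 = th[0] - wm[0], e1 = th[1] - wm[1], e2 = th[2] - wm[2];
        ws[0] += d0 * e0; ws[1] += d0 * e1; ws[2] += d0 * e2;
        ws[4] += d1 * e1; ws[5] += d1 * e2; ws[8] += d2 * e2;
        if (wn >= 200 && t % 100 == 0) {
          // scaled covariance 2.38^2/3 * Cov + jitter, then Cholesky
          double sc = 2.38 * 2.38 / 3.0 / (wn - 1);
          double C[9] = {ws[0] * sc, ws[1] * sc, ws[2] * sc,
                         ws[1] * sc, ws[4] * sc, ws[5] * sc,
                         ws[2] * sc, ws[5] * sc, ws[8] * sc};
          for (int j = 0; j < 3; ++j) C[4 * j] += 1e-12 + 1e-6 * C[4 * j];
          double l00 = std::sqrt(C[0]);
          double l10 = C[3] / l00;
          double l11s = C[4] - l10 * l10;
          double l20 = C[6] / l00;
          if (l11s > 0) {
            double l11 = std::sqrt(l11s);
            double l21 = (C[7] - l20 * l10) / l11;
            double l22s = C[8] - l20 * l20 - l21 * l21;
            if (l22s > 0) {
              L[0] = l00; L[3] = l10; L[4] = l11;
              L[6] = l20; L[7] = l21; L[8] = std::sqrt(l22s);
              if (!use_L) { use_L = true; lf = 0.0; } // restart step factor
            }
          }
        }
      }
    } else {
      if (accepted) ++acc_post;
      int post = t - n_burnin;
      if (post % thin == 0) out[kept++] = std::tanh(th[2]);
    }
  }
  return n_iter > 0 ? (double)acc_post / (double)n_iter : 0.0;
}

// --------------------------- summaries -------------------------------------

// type-7 quantile of a sorted vector
static double quantile7(const std::vector<double>& v, double p) {
  size_t N = v.size();
  if (N == 1) return v[0];
  double h = (double)(N - 1) * p;
  size_t lo = (size_t)std::floor(h);
  if (lo >= N - 1) return v[N - 1];
  return v[lo] + (h - lo) * (v[lo + 1] - v[lo]);
}

// Split-chain R-hat and effective sample size (rank-free, Geyer-truncated
// pair sums), computed from an n_keep x n_chains draw matrix.
static void diagnostics(const double* draws, int n_keep, int n_chains,
                        double* rhat, double* ess) {
  int n2 = n_keep / 2;
  int m = 2 * n_chains;
  if (n2 < 4) { *rhat = NA_REAL; *ess = NA_REAL; return; }

  std::vector<const double*> seq(m);
  for (int c = 0; c < n_chains; ++c) {
    seq[2 * c] = draws + (size_t)c * n_keep;
    seq[2 * c + 1] = draws + (size_t)c * n_keep + (n_keep - n2);
  }
  std::vector<double> mean(m), var(m);
  double grand = 0.0;
  for (int j = 0; j < m; ++j) {
    double mu = 0.0;
    for (int i = 0; i < n2; ++i) mu += seq[j][i];
    mu /= n2;
    mean[j] = mu;
    grand += mu;
    double v = 0.0;
    for (int i = 0; i < n2; ++i) { double d = seq[j][i] - mu; v += d * d; }
    var[j] = v / (n2 - 1);
  }
  grand /= m;
  double W = 0.0;
  for (int j = 0; j < m; ++j) W += var[j];
  W /= m;
  double B = 0.0;
  for (int j = 0; j < m; ++j) { double d = mean[j] - grand; B += d * d; }
  B *= (double)n2 / (m - 1);
  double var_plus = (double)(n2 - 1) / n2 * W + B / n2;

  if (W <= 0.0 || var_plus <= 0.0) { *rhat = 1.0; *ess = 0.0; return; }
  *rhat = std::sqrt(var_plus / W);

  // averaged autocovariance at lag t across split sequences
  auto acov = [&](int t) {
    double a = 0.0;
    for (int j = 0; j < m; ++j) {
      double sum = 0.0;
      for (int i = 0; i < n2 - t; ++i)
        sum += (seq[j][i] - mean[j]) * (seq[j][i + t] - mean[j]);
      a += sum / n2;
    }
    return a / m;
  };
  // integrated autocorrelation time via Geyer initial positive pairs:
  // tau = -1 + 2 * sum_k P_k, P_k = rho_{2k} + rho_{2k+1}, rho_0 = 1,
  // pairs truncated at the first negative and forced monotone non-increasing.
  int max_lag = n2 - 1;
  auto rho_at = [&](int t) {
    if (t == 0) return 1.0;
    return 1.0 - (W - acov(t)) / var_plus;
  };
  double tau = -1.0;
  double prev_pair = std::numeric_limits<double>::infinity();
  for (int k = 0; 2 * k + 1 <= max_lag; ++k) {
    double pair = rho_at(2 * k) + rho_at(2 * k + 1);
    if (pair < 0.0) break;
    if (pair > prev_pair) pair = prev_pair;
    prev_pair = pair;
    tau += 2.0 * pair;
  }
  double total = (double)m * n2;
  double e = total / std::max(tau, 1e-12);
  if (e > total) e = total;
  *ess = e;
}

static void summarize(const std::vector<double>& all, const double* draws,
                      int n_keep, int n_chains, double* out9) {
  size_t N = all.size();
  double mean = 0.0;
  for (double v : all) mean += v;
  mean /= N;
  double sd = 0.0;
  for (double v : all) { double d = v - mean; sd += d * d; }
  sd = std::sqrt(sd / (N - 1));
  std::vector<double> sorted(all);
  std::sort(sorted.begin(), sorted.end());
  double med = quantile7(sorted, 0.5);
  double lo = quantile7(sorted, 0.025);
  double hi = quantile7(sorted, 0.975);
  double rhat, ess;
  diagnostics(draws, n_keep, n_chains, &rhat, &ess);
  out9[0] = mean; out9[1] = sd; out9[2] = med; out9[3] = lo; out9[4] = hi;
  out9[5] = rhat; out9[6] = ess;
}

// ----------------------------- exports -------------------------------------

static Prior make_prior(double mu_scale, double sigma_scale, int rho_code,
                        double shrink_k) {
  Prior pr;
  pr.mu_scale = mu_scale;
  pr.sigma_scale = sigma_scale;
  pr.rho_code = rho_code;
  pr.shrink_k = shrink_k;
  return pr;
}

// Retained rho draws for one gene: matrix n_keep x n_chains. Chain c is
// seeded with seed + c + 1.
// [[Rcpp::export]]
NumericMatrix cpp_sample_rho(NumericVector suff, double seed,
                             double mu_scale, double sigma_scale,
                             int rho_code, double shrink_k,
                             int n_chains, int n_iter, int n_burnin,
                             int thin, bool adapt, double target_accept) {
  Suff raw = {suff[0], suff[1], suff[2], suff[3], suff[4], suff[5]};
  CSuff s = center_suff(raw);
  Prior pr = make_prior(mu_scale, sigma_scale, rho_code, shrink_k);
  int n_keep = n_iter / thin;
  NumericMatrix draws(n_keep, n_chains);
  for (int c = 0; c < n_chains; ++c) {
    run_chain(s, pr, (uint64_t)(seed + c + 1), n_burnin, n_iter, thin, adapt,
              target_accept, &draws(0, c));
  }
  return draws;
}

// Batch fit: one row of summaries per gene. Columns:
// rho_mean, rho_sd, rho_median, ci_lo, ci_hi, rhat, ess, accept_rate.
// [[Rcpp::export]]
NumericMatrix cpp_fit_batch(NumericMatrix suff, NumericVector seeds,
                            double mu_scale, double sigma_scale,
                            int rho_code, double shrink_k,
                            int n_chains, int n_iter, int n_burnin,
                            int thin, bool adapt, double target_accept) {
  int G = suff.nrow();
  if (seeds.size() != G) stop("length(seeds) must equal nrow(suff)");
  Prior pr = make_prior(mu_scale, sigma_scale, rho_code, shrink_k);
  int n_keep = n_iter / thin;
  NumericMatrix out(G, 8);
  colnames(out) = CharacterVector::create("rho_mean", "rho_sd", "rho_median",
                                          "ci_lo", "ci_hi", "rhat", "ess",
                                          "accept_rate");
  std::vector<double> draws((size_t)n_keep * n_chains);
  std::vector<double> all((size_t)n_keep * n_chains);
  for (int g = 0; g < G; ++g) {
    Suff raw = {suff(g, 0), suff(g, 1), suff(g, 2),
                suff(g, 3), suff(g, 4), suff(g, 5)};
    CSuff s = center_suff(raw);
    double acc = 0.0;
    for (int c = 0; c < n_chains; ++c) {
      acc += run_chain(s, pr, (uint64_t)(seeds[g] + c + 1), n_burnin, n_iter,
                       thin, adapt, target_accept,
                       draws.data() + (size_t)c * n_keep);
    }
    std::copy(draws.begin(), draws.end(), all.begin());
    double s9[9];
    summarize(all, draws.data(), n_keep, n_chains, s9);
    for (int k = 0; k < 7; ++k) out(g, k) = s9[k];
    out(g, 7) = acc / n_chains;
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Summaries computed from an externally supplied draw matrix; used so the
// single-fit path and the batch path share one summary implementation.
// [[Rcpp::export]]
NumericVector cpp_summarize_draws(NumericMatrix draws) {
  int n_keep = draws.nrow(), n_chains = draws.ncol();
  std::vector<double> all(draws.begin(), draws.end());
  double s9[9];
  summarize(all, draws.begin(), n_keep, n_chains, s9);
  NumericVector out(7);
  for (int k = 0; k < 7; ++k) out[k] = s9[k];
  out.names() = CharacterVector::create("rho_mean", "rho_sd", "rho_median",
                                        "ci_lo", "ci_hi", "rhat", "ess");
  return out;
}

// Mean-marginalized log target density on the sampling scale
// (log sigma1, log sigma2, atanh rho), exposed for testing: up to an
// additive constant it must equal the log of the numeric integral of the
// full five-parameter posterior density over the two means.
// [[Rcpp::export]]
double cpp_log_target(NumericVector theta, NumericVector suff,
                      double mu_scale, double sigma_scale,
                      int rho_code, double shrink_k) {
  Suff raw = {suff[0], suff[1], suff[2], suff[3], suff[4], suff[5]};
  CSuff s = center_suff(raw);
  Prior pr = make_prior(mu_scale, sigma_scale, rho_code, shrink_k);
  double th[3];
  for (int j = 0; j < 3; ++j) th[j] = theta[j];
  return log_target(th, s, pr);
}
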