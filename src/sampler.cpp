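#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// numerically stable inverse logit, safe for |eta| up to ~1e3
static inline double inv_logit(double eta) {
  if (eta >= 0.0) return 1.0 / (1.0 + std::exp(-eta));
  const double e = std::exp(eta);
  return e / (1.0 + e);
}

// Joint log posterior of the logistic-mean Gaussian-error model.
// par = c(beta, sigma); Z is the n x p design (intercept column included,
// year-dummy column included when the model has one). All normalizing
// constants are kept so the value matches a term-by-term density summation.
// sigma prior: half-normal(prior_sd) when sigma_flat == 0 (identical to a
// normal(0, prior_sd) truncated to the positive half-line), improper flat on
// (0, inf) when sigma_flat == 1.
static double log_post(const arma::vec& par, const arma::mat& Z,
                       const arma::vec& y, double prior_sd, int sigma_flat) {
  const arma::uword p = Z.n_cols;
  const double sigma = par[p];
  if (!(sigma > 0.0) || !std::isfinite(sigma)) return R_NegInf;
  double lp = 0.0;
  if (y.n_elem > 0) {
    const arma::vec eta = Z * par.head(p);
    for (arma::uword i = 0; i < y.n_elem; ++i)
      lp += R::dnorm(y[i], inv_logit(eta[i]), sigma, 1);
  }
  for (arma::uword j = 0; j < p; ++j)
    lp += R::dnorm(par[j], 0.0, prior_sd, 1);
  if (!sigma_flat)
    lp += R::dnorm(sigma, 0.0, prior_sd, 1) + M_LN2;
  return lp;
}

// [[Rcpp::export(name = ".log_post_cpp")]]
double log_post_cpp(const arma::vec& par, const arma::mat& Z,
                    const arma::vec& y, double prior_sd, int sigma_flat) {
  return log_post(par, Z, y, prior_sd, sigma_flat);
}

// One chain of adaptive random-walk Metropolis. The proposal starts from a
// supplied Cholesky factor (typically of a Laplace-approximation
// covariance). During warm-up it is adapted two ways (Haario-style): the
// covariance tracks the running covariance of visited states scaled by
// 2.38^2/d, and a global log-scale follows a Robbins-Monro recursion toward
// the target acceptance rate. Both are frozen after warm-up, so the
// retained draws come from a fixed-kernel Markov chain. Every thin-th
// post-warm-up state is retained. Uses R's RNG, so set.seed() governs the
// chain. Returns the ((iterations - warmup) / thin) x d matrix of retained
// draws, columns c(beta, sigma).
// [[Rcpp::export(name = ".run_chain_cpp")]]
arma::mat run_chain_cpp(const arma::mat& Z, const arma::vec& y,
                        double prior_sd, int sigma_flat,
                        int iterations, int warmup, int thin,
                        const arma::vec& init, const arma::mat& init_chol,
                        double target_accept) {
  const int d = init.n_elem;  // p regression terms + sigma
  arma::vec cur = init;
  double cur_lp = log_post(cur, Z, y, prior_sd, sigma_flat);
  if (!std::isfinite(cur_lp))
    stop("initial state has zero posterior density");

  const int n_keep = (iterations - warmup) / thin;
  arma::mat draws(n_keep, d);
  int kept = 0;
  double log_lambda = 0.0;
  arma::vec run_mean = cur;
  arma::mat run_m2(d, d, arma::fill::zeros);
  long n_seen = 1;
  const double base = 2.38 * 2.38 / d;
  arma::mat prop_chol = init_chol;

  for (int t = 1; t <= iterations; ++t) {
    if (t <= warmup && n_seen > 10 * d) {
      arma::mat S = base * (run_m2 / (double)(n_seen - 1));
      S.diag() += 1e-12;
      arma::mat L;
      if (arma::chol(L, S, "lower")) prop_chol = L;
    }
    const double lam = std::exp(log_lambda);
    arma::vec z(d);
    for (int j = 0; j < d; ++j) z[j] = norm_rand();
    const arma::vec prop = cur + lam * (prop_chol * z);
    const double prop_lp = log_post(prop, Z, y, prior_sd, sigma_flat);
    double alpha = 0.0;
    if (std::isfinite(prop_lp)) {
      alpha = std::exp(std::min(0.0, prop_lp - cur_lp));
      if (unif_rand() < alpha) {
        cur = prop;
        cur_lp = prop_lp;
      }
    }
    if (t <= warmup) {
      log_lambda += (alpha - target_accept) / std::pow((double)t, 0.6);
      ++n_seen;
      const arma::vec delta = cur - run_mean;
      run_mean += delta / (double)n_seen;
      run_m2 += delta * (cur - run_mean).t();
    } else if ((t - warmup) % thin == 0 && kept < n_keep) {
      draws.row(kept++) = cur.t();
    }
  }
  return draws;
}
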