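#include <Rcpp.h>
using namespace Rcpp;

// Concentration-dependent mixing moments for one element.
// w_k = p_k * conc_k / sum_j p_j conc_j
// mu  = sum_k w_k (mu_k + eps_mean)
// var = sum_k w_k^2 (sd_k^2 + eps_sd^2)   (process error only)
static inline void mix_moments(const std::vector<double> &p,
                               const NumericVector &mu,
                               const NumericVector &sd,
                               const NumericVector &conc,
                               double eps_mean, double eps_sd,
                               double &mu_mix, double &var_mix) {
  const int K = p.size();
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += p[k] * conc[k];
  mu_mix = 0.0;
  var_mix = 0.0;
  for (int k = 0; k < K; ++k) {
    double w = p[k] * conc[k] / tot;
    mu_mix += w * (mu[k] + eps_mean);
    var_mix += w * w * (sd[k] * sd[k] + eps_sd * eps_sd);
  }
}

// Log posterior kernel at additive-log-ratio coordinates z (length K-1).
// p = softmax(c(z, 0)); Dirichlet(alpha) prior with alr Jacobian
// log|J| = sum_k log p_k; independent-normal process likelihood per element.
// An infinite process variance makes that element's contribution constant
// (likelihood switched off), not -Inf.
static double log_post(const std::vector<double> &z,
                       std::vector<double> &p,
                       double d13C, double d15N,
                       const NumericVector &mu13, const NumericVector &sd13,
                       const NumericVector &mu15, const NumericVector &sd15,
                       const NumericVector &concC, const NumericVector &concN,
                       double e13m, double e13s, double e15m, double e15s,
                       const NumericVector &alpha) {
  const int K = p.size();
  double zmax = 0.0;
  for (int k = 0; k < K - 1; ++k) if (z[k] > zmax) zmax = z[k];
  double denom = std::exp(-zmax);
  for (int k = 0; k < K - 1; ++k) denom += std::exp(z[k] - zmax);
  for (int k = 0; k < K - 1; ++k) p[k] = std::exp(z[k] - zmax) / denom;
  p[K - 1] = std::exp(-zmax) / denom;

  double lp = 0.0;
  for (int k = 0; k < K; ++k) lp += alpha[k] * std::log(p[k]); // (a-1)logp + Jacobian logp

  double mu, var;
  mix_moments(p, mu13, sd13, concC, e13m, e13s, mu, var);
  if (R_finite(var)) {
    if (var <= 0.0) return (d13C == mu) ? lp : R_NegInf;
    lp += -0.5 * std::log(2.0 * M_PI * var) - (d13C - mu) * (d13C - mu) / (2.0 * var);
  }
  mix_moments(p, mu15, sd15, concN, e15m, e15s, mu, var);
  if (R_finite(var)) {
    if (var <= 0.0) return (d15N == mu) ? lp : R_NegInf;
    lp += -0.5 * std::log(2.0 * M_PI * var) - (d15N - mu) * (d15N - mu) / (2.0 * var);
  }
  return lp;
}

// Random-walk Metropolis on the alr transform of the diet simplex.
// Proposal scale adapts during burn-in (factor steps every 100 iterations
// toward 20-50% acceptance) and is frozen afterwards. Uses R's RNG, so
// set.seed() upstream controls the stream.
// [[Rcpp::export]]
List simm_sampler_cpp(double d13C, double d15N,
                      NumericVector mu13, NumericVector sd13,
                      NumericVector mu15, NumericVector sd15,
                      NumericVector concC, NumericVector concN,
                      double eps13_mean, double eps13_sd,
                      double eps15_mean, double eps15_sd,
                      NumericVector alpha,
                      NumericVector z_init,
                      int chain_length, int burn_in, int thin,
                      double step_init) {
  const int K = mu13.size();
  std::vector<double> z(z_init.begin(), z_init.end());
  std::vector<double> zprop(K - 1), p(K), pprop(K);

  double step = step_init;
  double lp = log_post(z, p, d13C, d15N, mu13, sd13, mu15, sd15,
                       concC, concN, eps13_mean, eps13_sd,
                       eps15_mean, eps15_sd, alpha);
  if (!R_finite(lp)) stop("non-finite log posterior at the initial point");

  const int n_keep = (chain_length - burn_in) / thin;
  NumericMatrix draws(n_keep, K);
  int kept = 0, acc_window = 0, acc_total = 0, n_post = 0;

  for (int it = 1; it <= chain_length; ++it) {
    for (int k = 0; k < K - 1; ++k) zprop[k] = z[k] + step * R::norm_rand();
    double lp_prop = log_post(zprop, pprop, d13C, d15N, mu13, sd13, mu15, sd15,
                              concC, concN, eps13_mean, eps13_sd,
                              eps15_mean, eps15_sd, alpha);
    if (R_finite(lp_prop) && std::log(R::unif_rand()) < lp_prop - lp) {
      z = zprop;
      p = pprop;
      lp = lp_prop;
      ++acc_window;
      if (it > burn_in) ++acc_total;
    }
    if (it <= burn_in) {
      if (it % 100 == 0) {
        double rate = acc_window / 100.0;
        if (rate > 0.5) step *= 1.2;
        else if (rate < 0.2) step /= 1.2;
        acc_window = 0;
      }
    } else {
      ++n_post;
      if ((it - burn_in) % thin == 0 && kept < n_keep) {
        for (int k = 0; k < K; ++k) draws(kept, k) = p[k];
        ++kept;
      }
    }
  }
  return List::create(
    _["draws"] = draws,
    _["acceptance"] = n_post > 0 ? (double)acc_total / n_post : NA_REAL,
    _["step"] = step
  );
}
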