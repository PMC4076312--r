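#include <Rcpp.h>
using namespace Rcpp;

// log N(x | mu, sigma)
static inline double ldnorm(double x, double mu, double sigma) {
  static const double LOG_SQRT_2PI = 0.9189385332046727;
  double z = (x - mu) / sigma;
  return -0.5 * z * z - std::log(sigma) - LOG_SQRT_2PI;
}

// One EM run for a univariate Gaussian mixture.
//
// Responsibilities are computed in log space (log-sum-exp) so that points far
// from every component do not underflow. A run is flagged degenerate as soon
// as any component SD drops below sigma_floor or any weight vanishes.
// The log-likelihood must be non-decreasing across iterations up to roundoff;
// `monotone` records whether that held (it is asserted by tests, not silently
// repaired).
// [[Rcpp::export]]
List em_gmm_cpp(NumericVector x, NumericVector mu0, NumericVector sigma0,
                NumericVector pi0, double tol, int max_iter,
                double sigma_floor) {
  const int n = x.size(), k = mu0.size();
  NumericVector mu = clone(mu0), sigma = clone(sigma0), pi = clone(pi0);
  NumericMatrix resp(n, k);
  double ll = R_NegInf, ll_prev = R_NegInf;
  bool converged = false, degenerate = false, monotone = true;
  int iter = 0;

  std::vector<double> inv_s(k), amp(k);
  for (iter = 1; iter <= max_iter; ++iter) {
    // E step. Densities are formed in linear space (one exp per term); only
    // a point whose total density underflows to 0 is redone via log-sum-exp.
    for (int j = 0; j < k; ++j) {
      inv_s[j] = 1.0 / sigma[j];
      amp[j] = pi[j] * inv_s[j] * 0.3989422804014327; // 1/sqrt(2*pi)
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int j = 0; j < k; ++j) {
        double z = (x[i] - mu[j]) * inv_s[j];
        resp(i, j) = amp[j] * std::exp(-0.5 * z * z);
        tot += resp(i, j);
      }
      if (tot > 0.0) {
        ll += std::log(tot);
        for (int j = 0; j < k; ++j) resp(i, j) /= tot;
      } else {
        double m = R_NegInf;
        for (int j = 0; j < k; ++j) {
          double lw = std::log(pi[j]) + ldnorm(x[i], mu[j], sigma[j]);
          resp(i, j) = lw;
          if (lw > m) m = lw;
        }
        if (!std::isfinite(m)) { degenerate = true; break; }
        double s = 0.0;
        for (int j = 0; j < k; ++j) s += std::exp(resp(i, j) - m);
        double lse = m + std::log(s);
        ll += lse;
        for (int j = 0; j < k; ++j) resp(i, j) = std::exp(resp(i, j) - lse);
      }
    }
    if (degenerate) break;
    if (ll < ll_prev - 1e-8 * std::max(1.0, std::fabs(ll_prev))) monotone = false;

    // M step
    for (int j = 0; j < k; ++j) {
      double nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) { nk += resp(i, j); sx += resp(i, j) * x[i]; }
      if (nk <= 1e-10) { degenerate = true; break; }
      double mj = sx / nk, sv = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - mj;
        sv += resp(i, j) * d * d;
      }
      mu[j] = mj;
      sigma[j] = std::sqrt(sv / nk);
      pi[j] = nk / n;
      if (sigma[j] < sigma_floor) { degenerate = true; break; }
    }
    if (degenerate) break;

    if (std::fabs(ll - ll_prev) < tol) { converged = true; break; }
    ll_prev = ll;
  }

  return List::create(_["mu"] = mu, _["sigma"] = sigma, _["pi"] = pi,
                      _["loglik"] = ll, _["iter"] = iter,
                      _["converged"] = converged, _["degenerate"] = degenerate,
                      _["monotone"] = monotone);
}

// Mixture log-likelihood of a data vector, log-sum-exp stabilised.
// [[Rcpp::export]]
double loglik_gmm_cpp(NumericVector x, NumericVector mu, NumericVector sigma,
                      NumericVector pi) {
  const int n = x.size(), k = mu.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = R_NegInf;
    std::vector<double> lw(k);
    for (int j = 0; j < k; ++j) {
      lw[j] = std::log(pi[j]) + ldnorm(x[i], mu[j], sigma[j]);
      if (lw[j] > m) m = lw[j];
    }
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::exp(lw[j] - m);
    ll += m + std::log(s);
  }
  return ll;
}
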