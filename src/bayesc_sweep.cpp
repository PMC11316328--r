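#include <Rcpp.h>
using namespace Rcpp;

// One Gibbs sweep over all markers of a BayesC (spike-and-slab, common
// effect variance) regression. `r` is the current full residual
// y* - mu - X beta on the training rows and is updated in place, as are
// `beta` and `delta`. Uses R's RNG so set.seed() governs reproducibility.
//
// Per marker j: integrate beta_j out to get the inclusion odds
//   c_j = x_j'x_j / s2e + 1 / s2b,   m_j = (x_j' r_{-j} / s2e) / c_j
//   log BF = log(pi/(1-pi)) + 0.5 (log(1/s2b) - log c_j + m_j^2 c_j)
// then draw delta_j ~ Bernoulli, and beta_j | delta_j=1 ~ N(m_j, 1/c_j).
// [[Rcpp::export]]
List bayesc_sweep(const NumericMatrix& X, NumericVector r,
                  NumericVector beta, IntegerVector delta,
                  const NumericVector& x2, double s2b, double s2e,
                  double pi) {
  int n = X.nrow(), p = X.ncol();
  double log_prior_odds = std::log(pi) - std::log1p(-pi);
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double xr = 0.0;
    for (int i = 0; i < n; ++i) xr += xj[i] * r[i];
    xr += x2[j] * beta[j];  // residual without marker j's contribution
    double c = x2[j] / s2e + 1.0 / s2b;
    double m = (xr / s2e) / c;
    double log_bf = log_prior_odds +
      0.5 * (-std::log(s2b) - std::log(c) + m * m * c);
    double p_in = 1.0 / (1.0 + std::exp(-log_bf));
    double old = beta[j];
    if (unif_rand() < p_in) {
      double bnew = m + norm_rand() / std::sqrt(c);
      delta[j] = 1;
      beta[j] = bnew;
    } else {
      delta[j] = 0;
      beta[j] = 0.0;
    }
    double diff = old - beta[j];
    if (diff != 0.0) {
      for (int i = 0; i < n; ++i) r[i] += xj[i] * diff;
    }
  }
  return List::create(_["r"] = r, _["beta"] = beta, _["delta"] = delta);
}
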