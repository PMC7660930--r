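#include <Rcpp.h>
using namespace Rcpp;

// One cyclic coordinate-ascent sweep over SNPs for the spike-and-slab
// variational approximation. For SNP k (in the supplied order):
//   s2_k  = sigma2 / (xx_k + 1/sigma_beta2)
//   mu_k  = s2_k / sigma2 * x_k' (resid + x_k * alpha_k * mu_k)
//   logit(alpha_k) = prior_logit_k + 0.5 log(s2_k / (sigma2 sigma_beta2))
//                    + mu_k^2 / (2 s2_k)
// resid = Y - X (alpha o mu) is maintained incrementally so the sweep costs
// O(n p). Updates alpha, mu, s2 and resid in place.
// [[Rcpp::export]]
void vb_sweep_inplace(const NumericMatrix& X, const NumericVector& xx,
                      const NumericVector& prior_logit, double sigma2,
                      double sigma_beta2, NumericVector alpha,
                      NumericVector mu, NumericVector s2,
                      NumericVector resid, const IntegerVector& order) {
  const int n = X.nrow();
  const double log_slab = std::log(sigma2 * sigma_beta2);
  for (int idx = 0; idx < order.size(); ++idx) {
    const int k = order[idx];
    const double s2k = sigma2 / (xx[k] + 1.0 / sigma_beta2);
    // x_k' resid plus the part of the fit currently attributed to SNP k
    double dot = 0.0;
    const double rk_old = alpha[k] * mu[k];
    for (int i = 0; i < n; ++i) dot += X(i, k) * resid[i];
    dot += xx[k] * rk_old;
    const double muk = s2k * dot / sigma2;
    const double lo = prior_logit[k] + 0.5 * (std::log(s2k) - log_slab) +
      muk * muk / (2.0 * s2k);
    double ak;
    if (lo > 0) ak = 1.0 / (1.0 + std::exp(-lo));
    else { const double e = std::exp(lo); ak = e / (1.0 + e); }
    const double rk_new = ak * muk;
    const double delta = rk_new - rk_old;
    if (delta != 0.0) {
      for (int i = 0; i < n; ++i) resid[i] -= X(i, k) * delta;
    }
    alpha[k] = ak; mu[k] = muk; s2[k] = s2k;
  }
}
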