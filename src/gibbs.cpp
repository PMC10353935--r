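#include <Rcpp.h>
using namespace Rcpp;

// Spike-and-slab Gibbs sampler for one LD block on the standardized scale.
//
// Model: beta_hat = R beta + e, e ~ N(0, R/n) (marginal effects); prior
// beta_j ~ p * N(0, sigma2) + (1 - p) * delta_0. Per-variant conditional
// update uses the residualized marginal effect given current values of the
// block's LD partners. Returns the Rao-Blackwellised posterior mean
// (average over kept iterations of inclusion-probability x conditional
// slab mean), which has much lower Monte-Carlo error than averaging draws.
//
// Uses R's RNG stream, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".gibbs_block")]]
NumericVector gibbs_block(const NumericMatrix& R,
                          const NumericVector& beta_hat,
                          const NumericVector& n_eff,
                          double sigma2, double p,
                          int burn_in, int n_iter) {
  const int m = R.ncol();
  std::vector<double> beta(m, 0.0);      // current sampled effects
  std::vector<double> rbeta(m, 0.0);     // R %*% beta, maintained incrementally
  NumericVector post(m);
  const double log_p = std::log(p);
  const double log_q = p < 1.0 ? std::log(1.0 - p) : R_NegInf;

  RNGScope scope;
  for (int it = 0; it < burn_in + n_iter; ++it) {
    for (int j = 0; j < m; ++j) {
      const double nj = n_eff[j];
      const double resid = beta_hat[j] - (rbeta[j] - beta[j]); // exclude self
      const double s2_post = sigma2 / (nj * sigma2 + 1.0);
      const double mu_post = resid * (nj * sigma2) / (nj * sigma2 + 1.0);
      // log densities of resid under slab N(0, sigma2 + 1/n) vs spike N(0, 1/n)
      const double v1 = sigma2 + 1.0 / nj;
      const double v0 = 1.0 / nj;
      const double l1 = log_p - 0.5 * std::log(v1) - 0.5 * resid * resid / v1;
      const double l0 = log_q - 0.5 * std::log(v0) - 0.5 * resid * resid / v0;
      double p1;
      if (p >= 1.0) p1 = 1.0;
      else {
        const double mx = std::max(l1, l0);
        p1 = std::exp(l1 - mx) / (std::exp(l1 - mx) + std::exp(l0 - mx));
      }
      double bnew = 0.0;
      if (unif_rand() < p1) bnew = mu_post + std::sqrt(s2_post) * norm_rand();
      const double diff = bnew - beta[j];
      if (diff != 0.0) {
        for (int k = 0; k < m; ++k) rbeta[k] += R(k, j) * diff;
        beta[j] = bnew;
      }
      if (it >= burn_in) post[j] += p1 * mu_post;
    }
  }
  for (int j = 0; j < m; ++j) post[j] /= n_iter;
  return post;
}
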