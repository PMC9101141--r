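#include <Rcpp.h>
using namespace Rcpp;

// Single-site Metropolis sweep over the spatially varying coefficient field.
//
// For each unit i, proposes beta_i' = beta_i + scale * N(0, I_K) and accepts
// with the usual ratio combining the Poisson log-likelihood change
//   sum_k [ y_ik (b'_k - b_k) ndi_i - exp(alpha_k) E_ik (e^{b'_k ndi_i} - e^{b_k ndi_i}) ]
// and the intrinsic MVCAR kernel change
//   -1/2 sum_{j in N(i)} [ (b'-b_j)' Omega (b'-b_j) - (b-b_j)' Omega (b-b_j) ].
// All randomness goes through R's RNG so set.seed() governs reproducibility.
// beta is modified in place; the caller owns the matrix.
//
// nbr / nbr_ptr: 0-based CSR neighbor lists (neighbors of i are
// nbr[nbr_ptr[i] .. nbr_ptr[i+1]-1]).
// prop_chol: lower-triangular K x K factor shaping the proposal increment
// (scale * prop_chol %*% z); the identity recovers an isotropic walk.
// use_lik = 0 disables the likelihood term (prior-only sampling).
// [[Rcpp::export]]
int beta_sweep_cpp(NumericMatrix beta, const NumericMatrix y,
                   const NumericMatrix E, const NumericVector alpha,
                   const NumericVector ndi, const IntegerVector nbr,
                   const IntegerVector nbr_ptr, const NumericMatrix omega,
                   const double scale, const NumericMatrix prop_chol,
                   const int use_lik) {
  const int n = beta.nrow(), K = beta.ncol();
  int accepts = 0;
  std::vector<double> prop(K), cur(K), z(K);
  for (int i = 0; i < n; ++i) {
    double logr = 0.0;
    for (int k = 0; k < K; ++k) z[k] = R::norm_rand();
    for (int k = 0; k < K; ++k) {
      cur[k] = beta(i, k);
      double step = 0.0;
      for (int l = 0; l <= k; ++l) step += prop_chol(k, l) * z[l];
      prop[k] = cur[k] + scale * step;
    }
    if (use_lik) {
      const double d = ndi[i];
      for (int k = 0; k < K; ++k) {
        const double ea = std::exp(alpha[k]) * E(i, k);
        logr += y(i, k) * (prop[k] - cur[k]) * d
              - ea * (std::exp(prop[k] * d) - std::exp(cur[k] * d));
      }
    }
    // prior kernel change over neighbors
    for (int m = nbr_ptr[i]; m < nbr_ptr[i + 1]; ++m) {
      const int j = nbr[m];
      double qprop = 0.0, qcur = 0.0;
      for (int k = 0; k < K; ++k) {
        double dp = prop[k] - beta(j, k);
        double dc = cur[k] - beta(j, k);
        for (int l = 0; l < K; ++l) {
          qprop += dp * omega(k, l) * (prop[l] - beta(j, l));
          qcur  += dc * omega(k, l) * (cur[l]  - beta(j, l));
        }
      }
      logr += -0.5 * (qprop - qcur);
    }
    if (std::isfinite(logr) && std::log(R::unif_rand()) < logr) {
      for (int k = 0; k < K; ++k) beta(i, k) = prop[k];
      ++accepts;
    }
  }
  return accepts;
}

// Poisson log-likelihood including the log(y!) constant:
// sum_ik [ y log(mu) - mu - lgamma(y+1) ], mu = E * exp(alpha_k + beta ndi).
// [[Rcpp::export]]
double poisson_loglik_cpp(const NumericMatrix y, const NumericMatrix E,
                          const NumericVector alpha, const NumericMatrix beta,
                          const NumericVector ndi) {
  const int n = y.nrow(), K = y.ncol();
  double ll = 0.0;
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i) {
      const double lmu = std::log(E(i, k)) + alpha[k] + beta(i, k) * ndi[i];
      if (!std::isfinite(lmu)) return R_NegInf;
      ll += y(i, k) * lmu - std::exp(lmu) - R::lgammafn(y(i, k) + 1.0);
    }
  }
  return ll;
}
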