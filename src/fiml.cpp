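// Full-information maximum likelihood kernel.
//
// Cases are grouped by missingness pattern; each pattern block is reduced
// to its sufficient statistics (n, mean, scatter), so one likelihood
// evaluation costs O(patterns * p^3) independent of sample size. The
// result is identical to the casewise sum of multivariate normal
// log-densities over each case's observed subset.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// blocks: list of list(cols = 0-based indices, n, ybar, S) where S is the
// within-block scatter matrix with divisor n. Returns NA_real_ when the
// implied covariance restricted to any pattern is not positive definite.
// [[Rcpp::export]]
double fiml_blocks_loglik(List blocks, const arma::vec& mu,
                          const arma::mat& Sigma) {
  const double log2pi = std::log(2.0 * M_PI);
  double ll = 0.0;
  if (!mu.is_finite() || !Sigma.is_finite()) return NA_REAL;
  try {
  for (int b = 0; b < blocks.size(); ++b) {
    List blk = blocks[b];
    arma::uvec cols = as<arma::uvec>(blk["cols"]);
    double n = as<double>(blk["n"]);
    arma::vec ybar = as<arma::vec>(blk["ybar"]);
    arma::mat S = as<arma::mat>(blk["S"]);
    const int k = cols.n_elem;
    arma::vec mus = mu.elem(cols);
    arma::mat Sig = Sigma.submat(cols, cols);
    Sig = 0.5 * (Sig + Sig.t());   // guard against rounding asymmetry
    arma::mat L;
    bool ok = false;
    try { ok = arma::chol(L, Sig, "lower"); } catch (...) { return NA_REAL; }
    if (!ok) return NA_REAL;
    if (L.diag().min() < 1e-10 * (1.0 + Sig.diag().max())) return NA_REAL;
    double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    arma::mat M1 = arma::solve(arma::trimatl(L), S);
    arma::mat M2 = arma::solve(arma::trimatl(L), M1.t());
    double tr = arma::trace(M2);
    arma::vec d = arma::solve(arma::trimatl(L), ybar - mus);
    double quad = arma::dot(d, d);
    ll += -0.5 * n * (k * log2pi + logdet + tr + quad);
  }
  } catch (...) { return NA_REAL; }
  if (std::isnan(ll)) return NA_REAL;
  return ll;
}
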