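// GLS likelihood cache for the transformed Brownian-motion covariance.
//
// The covariance entry for tips (i, j) is the kappa-depth of their MRCA:
//   depth_k(v) = sum over root->v edges of b^kappa,
// followed by the elementwise delta power and the lambda off-diagonal
// scaling. The Metropolis sampler calls this once per transform proposal,
// so the whole rebuild (depth accumulation, table lookup, Cholesky and
// the whitening solves) lives here. Inputs are pre-flattened 0-based
// index vectors so no per-call conversion copies are made.

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List gls_cache_cpp(IntegerVector M0,      // n*n MRCA node ids, 0-based, col-major
                   IntegerVector par0,    // preorder edge parents, 0-based
                   IntegerVector child0,  // preorder edge children, 0-based
                   NumericVector b,       // preorder branch lengths
                   int nnode,
                   double lambda, double delta, double kappa,
                   NumericVector y, NumericMatrix X) {
  const int n = y.size(), p = X.ncol(), ne = child0.size();
  std::vector<double> depthk(nnode, 0.0);
  for (int k = 0; k < ne; ++k) {
    const double bl = b[k];
    const double bk = (bl == 0.0) ? 0.0
                     : (kappa == 1.0 ? bl : std::pow(bl, kappa));
    depthk[child0[k]] = depthk[par0[k]] + bk;
  }
  arma::mat C(n, n);
  double* cp = C.memptr();
  const int* mp = INTEGER(M0);
  const int nn = n * n;
  if (delta == 1.0) {
    for (int i = 0; i < nn; ++i) cp[i] = depthk[mp[i]];
  } else {
    for (int i = 0; i < nn; ++i) cp[i] = std::pow(depthk[mp[i]], delta);
  }
  if (lambda != 1.0) {
    const arma::vec d = C.diag();
    C *= lambda;
    C.diag() = d;
  }
  arma::mat L;
  if (!arma::chol(L, C, "lower")) {
    return List::create(Named("ok") = false);
  }
  const double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  const arma::vec yv(const_cast<double*>(y.begin()), n, false, true);
  const arma::mat Xv(const_cast<double*>(X.begin()), n, p, false, true);
  arma::vec yt = arma::solve(arma::trimatl(L), yv);
  arma::mat Xt = arma::solve(arma::trimatl(L), Xv);
  return List::create(Named("ok") = true,
                      Named("logdet") = logdet,
                      Named("yt") = yt,
                      Named("Xt") = Xt);
}
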