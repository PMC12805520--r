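// ReLU MLP forward/backward, C++ hot path (BLAS matmuls via Armadillo,
// no intermediate R allocations). Mirrors the R reference in R/nn.R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List mlp_forward_cpp(List W, List b, const arma::mat& X) {
  const int L = W.size();
  List acts(L + 1);
  acts[0] = X;
  arma::mat A = X;
  for (int l = 0; l < L; ++l) {
    arma::mat Wl = as<arma::mat>(W[l]);
    arma::rowvec bl = as<arma::rowvec>(b[l]);
    A = A * Wl;
    A.each_row() += bl;
    if (l < L - 1) A.transform([](double v) { return v > 0.0 ? v : 0.0; });
    acts[l + 1] = A;
  }
  return List::create(_["out"] = A, _["acts"] = acts);
}

// [[Rcpp::export]]
List mlp_backward_cpp(List W, List acts, const arma::mat& gout) {
  const int L = W.size();
  List gW(L), gb(L);
  arma::mat g = gout;
  for (int l = L - 1; l >= 0; --l) {
    arma::mat a = as<arma::mat>(acts[l]);
    gW[l] = a.t() * g;
    gb[l] = arma::sum(g, 0);
    arma::mat Wl = as<arma::mat>(W[l]);
    g = g * Wl.t();
    if (l > 0) g %= arma::conv_to<arma::mat>::from(a > 0.0);
  }
  return List::create(_["W"] = gW, _["b"] = gb, _["gin"] = g);
}
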