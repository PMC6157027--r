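// Divide-and-conquer symmetric eigendecomposition; the hot spot of the
// profiled variance-component fitter (one decomposition per covariance
// evaluation).
#include <RcppArmadillo.h>

// [[Rcpp::export]]
Rcpp::List eigSym(const arma::mat& K) {
  arma::vec d;
  arma::mat U;
  if (!arma::eig_sym(d, U, K, "dc"))
    Rcpp::stop("symmetric eigendecomposition failed");
  return Rcpp::List::create(Rcpp::Named("values") = d,
                            Rcpp::Named("vectors") = U);
}
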