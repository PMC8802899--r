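#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Frobenius-norm multiplicative updates (Lee-Seung) for NMF.
// Deterministic given the initial factors; returns the per-iteration
// objective so monotonicity is checkable from R.

// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& D, arma::mat W, arma::mat C,
                      double tol, int max_iter) {
  const double eps = 1e-12;
  arma::vec obj(max_iter);
  double prev = arma::accu(arma::square(D - W * C));
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    C %= (W.t() * D) / (W.t() * W * C + eps);
    W %= (D * C.t()) / (W * (C * C.t()) + eps);
    double cur = arma::accu(arma::square(D - W * C));
    obj(it) = cur;
    ++it;
    if (prev > 0 && std::fabs(prev - cur) / prev < tol) {
      converged = true;
      break;
    }
    prev = cur;
  }
  return Rcpp::List::create(Rcpp::_["W"] = W, Rcpp::_["C"] = C,
                            Rcpp::_["objective"] = obj.head(it),
                            Rcpp::_["iterations"] = it,
                            Rcpp::_["converged"] = converged);
}
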