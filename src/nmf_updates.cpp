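// Multiplicative-update loop for the Frobenius NMF objective.
// H <- H * (W'V) / (W'W H + eps); W <- W * (V H') / (W H H' + eps).
// The RSS is evaluated exactly each iteration from cached Gram products:
// ||V - WH||^2 = ||V||^2 - 2<W'V, H> + <W'W, HH'>.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol) {
  const double eps = 1e-12;
  const double normV2 = arma::accu(arma::square(V));
  std::vector<double> trace;
  trace.reserve(max_iter + 1);

  arma::mat WtV = W.t() * V;
  arma::mat WtW = W.t() * W;
  double rss = normV2 - 2.0 * arma::accu(WtV % H) +
    arma::accu(WtW % (H * H.t()));
  trace.push_back(rss);

  bool converged = false;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    H = H % (WtV / (WtW * H + eps));
    arma::mat VHt = V * H.t();
    arma::mat HHt = H * H.t();
    W = W % (VHt / (W * HHt + eps));
    if (!W.is_finite() || !H.is_finite()) {
      Rcpp::stop("NaN encountered in NMF updates");
    }
    WtV = W.t() * V;
    WtW = W.t() * W;
    const double prev = trace.back();
    rss = normV2 - 2.0 * arma::accu(WtV % H) +
      arma::accu(WtW % (H * H.t()));
    trace.push_back(rss);
    if ((prev - rss) < tol * std::max(prev, eps)) {
      converged = true;
      break;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("rss") = std::max(rss, 0.0),
    Rcpp::Named("trace") = trace,
    Rcpp::Named("n_iter") = iter,
    Rcpp::Named("converged") = converged);
}
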