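// Multiplicative-update Frobenius NMF kernels.
// X (G x N) ~ W (G x k) * H (k x N), all nonnegative.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double EPS = 1e-12;

// [[Rcpp::export]]
Rcpp::List nmf_mu(const arma::mat& X, arma::mat W, arma::mat H,
                  int max_iter, double tol, int check_every) {
  double prev_err = datum::inf;
  double err = prev_err;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // H update
    mat WtX = W.t() * X;
    mat WtWH = (W.t() * W) * H;
    H %= WtX / (WtWH + EPS);
    // W update
    mat XHt = X * H.t();
    mat WHHt = W * (H * H.t());
    W %= XHt / (WHHt + EPS);
    if (it % check_every == 0 || it == max_iter) {
      err = norm(X - W * H, "fro");
      if (std::isfinite(prev_err) &&
          std::fabs(prev_err - err) <= tol * std::max(prev_err, EPS))
        break;
      prev_err = err;
    }
  }
  err = norm(X - W * H, "fro");
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("error") = err,
                            Rcpp::Named("iterations") = std::min(it, max_iter));
}

// Nonnegative least-squares fit of H with W fixed (multiplicative updates).
// [[Rcpp::export]]
Rcpp::List nmf_fit_usage(const arma::mat& X, const arma::mat& W, arma::mat H,
                         int max_iter, double tol, int check_every) {
  mat WtX = W.t() * X;
  mat WtW = W.t() * W;
  double prev_err = datum::inf;
  for (int it = 1; it <= max_iter; ++it) {
    H %= WtX / (WtW * H + EPS);
    if (it % check_every == 0 || it == max_iter) {
      double err = norm(X - W * H, "fro");
      if (std::isfinite(prev_err) &&
          std::fabs(prev_err - err) <= tol * std::max(prev_err, EPS))
        break;
      prev_err = err;
    }
  }
  double err = norm(X - W * H, "fro");
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("error") = err);
}
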