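// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Sum-of-block Gaussian kernel between row sets A (evaluation) and B
// (training): K_ij = sum_b exp(-||A_i,b - B_j,b||^2 / (2 sigma^2)), blocks
// of m columns.  Because the kernel is additive over blocks, the kernel of
// a [target past, source past] design equals K_target + K_source, which
// lets connectivity() precompute one kernel per channel (and per
// surrogate) and reuse it across all ordered pairs.
// [[Rcpp::export]]
arma::mat nw_kernel_blocks(const arma::mat& A, const arma::mat& B,
                           double sigma, int m) {
  const arma::uword nb = A.n_cols / m;
  const double gam = 1.0 / (2.0 * sigma * sigma);
  arma::mat K(A.n_rows, B.n_rows, arma::fill::zeros);
  for (arma::uword b = 0; b < nb; ++b) {
    arma::mat Ab = A.cols(b * m, (b + 1) * m - 1);
    arma::mat Bb = B.cols(b * m, (b + 1) * m - 1);
    arma::vec sa = arma::sum(arma::square(Ab), 1);
    arma::vec sb = arma::sum(arma::square(Bb), 1);
    arma::mat D = -2.0 * (Ab * Bb.t());
    D.each_col() += sa;
    D.each_row() += sb.t();
    K += arma::exp(-gam * D);
  }
  return K;
}

static double nw_err_from_kernel(const arma::mat& K, const arma::mat& Ytr,
                                 const arma::mat& Yte) {
  arma::vec norm = arma::sum(K, 1);
  norm.clamp(1e-12, arma::datum::inf);
  arma::mat pred = K * Ytr;
  pred.each_col() /= norm;
  return arma::mean(arma::mean(arma::square(Yte - pred)));
}

// Granger-causality values for one target against many candidate sources.
// Ky: target-past kernel (test x train); Kxs: list of source-past kernels.
// Returns c(err_restricted, gc_1, ..., gc_n) with gc floored at 0.
// [[Rcpp::export]]
Rcpp::NumericVector nw_gc_many(const arma::mat& Ky, const arma::mat& Ytr,
                               const arma::mat& Yte, Rcpp::List Kxs) {
  const int n = Kxs.size();
  Rcpp::NumericVector out(n + 1);
  double err_r = nw_err_from_kernel(Ky, Ytr, Yte);
  out[0] = err_r;
  for (int i = 0; i < n; ++i) {
    arma::mat Kx = Rcpp::as<arma::mat>(Kxs[i]);
    double err_f = nw_err_from_kernel(Ky + Kx, Ytr, Yte);
    out[i + 1] = (err_r <= DBL_EPSILON) ? 0.0
                 : std::max(0.0, std::log(err_r / err_f));
  }
  return out;
}
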