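// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Nadaraya-Watson kernel regression holdout error, the prediction-error
// primitive of the symbolic nonlinear Granger causality stage.
// The kernel is ADDITIVE over m-dimensional blocks (one block per lagged
// ordinal pattern): k(u, v) = sum_b exp(-||u_b - v_b||^2 / (2 sigma^2)).
// The additive form keeps the per-block Gaussian geometry while avoiding
// the dimensionality dilution of a product kernel when the conditioning
// set doubles (restricted vs full model).
// Fit on (Ftr, Ytr), return mean squared prediction error on (Fte, Yte).
// [[Rcpp::export]]
double nw_holdout_mse(const arma::mat& Ftr, const arma::mat& Ytr,
                      const arma::mat& Fte, const arma::mat& Yte,
                      double sigma, int m) {
  const arma::uword nb = Ftr.n_cols / m;
  const double gam = 1.0 / (2.0 * sigma * sigma);
  arma::mat K(Fte.n_rows, Ftr.n_rows, arma::fill::zeros);
  for (arma::uword b = 0; b < nb; ++b) {
    arma::mat A = Fte.cols(b * m, (b + 1) * m - 1);
    arma::mat B = Ftr.cols(b * m, (b + 1) * m - 1);
    arma::vec sa = arma::sum(arma::square(A), 1);
    arma::vec sb = arma::sum(arma::square(B), 1);
    arma::mat D = -2.0 * (A * B.t());
    D.each_col() += sa;
    D.each_row() += sb.t();
    K += arma::exp(-gam * D);
  }
  arma::vec norm = arma::sum(K, 1);
  norm.clamp(1e-12, arma::datum::inf);
  arma::mat pred = (K * Ytr);
  pred.each_col() /= norm;
  arma::mat R = Yte - pred;
  return arma::mean(arma::mean(arma::square(R)));
}
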