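// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// IAAFT surrogate core.  For each column of init_perm (1-based initial
// shuffles drawn in R so RNG reproducibility stays with R), iterate
// spectral-magnitude restoration and amplitude rank-remapping until the
// rank permutation stabilizes or max_iter is reached.  The sorted values of
// every surrogate equal the sorted original values exactly.
// [[Rcpp::export]]
arma::mat iaaft_cpp(const arma::vec& series, const arma::imat& init_perm,
                    int max_iter) {
  const arma::uword n = series.n_elem;
  const arma::uword ns = init_perm.n_cols;
  arma::vec amp = arma::sort(series);
  arma::vec mag = arma::abs(arma::fft(series));
  arma::mat out(n, ns);
  for (arma::uword s = 0; s < ns; ++s) {
    arma::vec x(n);
    for (arma::uword i = 0; i < n; ++i) x[i] = series[init_perm(i, s) - 1];
    arma::uvec prev_rank(n, arma::fill::zeros);
    for (int it = 0; it < max_iter; ++it) {
      arma::cx_vec X = arma::fft(x);
      // restore original spectral magnitudes, keep phases
      for (arma::uword i = 0; i < n; ++i) {
        double a = std::abs(X[i]);
        X[i] = (a > 0) ? X[i] * (mag[i] / a)
                       : std::complex<double>(mag[i], 0.0);
      }
      arma::vec y = arma::real(arma::ifft(X));
      arma::uvec ord = arma::stable_sort_index(y);
      arma::uvec rank(n);
      for (arma::uword i = 0; i < n; ++i) rank[ord[i]] = i;
      for (arma::uword i = 0; i < n; ++i) x[i] = amp[rank[i]];
      if (arma::all(rank == prev_rank)) break;
      prev_rank = rank;
    }
    out.col(s) = x;
  }
  return out;
}
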