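#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Ordinal-pattern symbolization of a series.
// Windows are forward in time: [x_t, x_{t+tau}, ..., x_{t+(m-1)tau}],
// t = 1..n-(m-1)tau.  Each window maps to the permutation that sorts it
// ascending (stable: ties broken by first occurrence) and to the
// lexicographic rank of that permutation in 0..m!-1.
// Returns list(patterns = count x m integer matrix (0-based argsort),
//              symbols  = integer vector of lexicographic ranks).
// [[Rcpp::export]]
List ordinal_symbolize_cpp(const NumericVector& x, int m, int tau) {
  const int n = x.size();
  const int count = n - (m - 1) * tau;
  if (m < 2) stop("embedding dimension m must be >= 2");
  if (tau < 1) stop("delay tau must be >= 1");
  if (count < 1) stop("series too short for embedding: need n > (m-1)*tau");
  IntegerMatrix patterns(count, m);
  IntegerVector symbols(count);
  std::vector<int> idx(m);
  // factorials for the Lehmer-code lexicographic rank
  std::vector<int> fact(m, 1);
  for (int i = 1; i < m; ++i) fact[i] = fact[i - 1] * i;
  for (int t = 0; t < count; ++t) {
    for (int j = 0; j < m; ++j) idx[j] = j;
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      return x[t + a * tau] < x[t + b * tau];
    });
    int rank = 0;
    for (int j = 0; j < m; ++j) {
      patterns(t, j) = idx[j];
      int smaller = 0;
      for (int k = j + 1; k < m; ++k)
        if (idx[k] < idx[j]) ++smaller;
      rank += smaller * fact[m - 1 - j];
    }
    symbols[t] = rank;
  }
  return List::create(_["patterns"] = patterns, _["symbols"] = symbols);
}
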