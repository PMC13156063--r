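#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive-history LZ76 phrase count, Kaspar-Schuster scanning procedure.
// bits must be 0/1. Returns the number of phrases c(n).
// [[Rcpp::export]]
int lz76_count_cpp(const IntegerVector& bits) {
  const int n = bits.size();
  if (n == 0) stop("empty sequence");
  if (n == 1) return 1;
  int c = 1;       // first symbol is always a new phrase
  int i = 0;       // start of the history prefix matched against
  int k = 1;       // current extension length
  int l = 1;       // start of the phrase currently being parsed
  int k_max = 1;
  while (true) {
    if (bits[i + k - 1] == bits[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > k_max) k_max = k;
      ++i;
      if (i == l) {          // no prefix reproduces the extension: new phrase
        ++c;
        l += k_max;
        if (l + 1 > n) break;
        i = 0;
        k = 1;
        k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
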