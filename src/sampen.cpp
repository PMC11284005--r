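#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy of a series: -log(A/B) with template length m, tolerance r
// (Chebyshev distance), self-matches excluded.  Returns NA when no matches.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1 || r <= 0) return NA_REAL;
  long long B = 0, A = 0;
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
      }
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}
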