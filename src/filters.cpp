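#include <Rcpp.h>
using namespace Rcpp;

static std::vector<double> iir_pass(const std::vector<double>& b,
                                    const std::vector<double>& a,
                                    const std::vector<double>& x) {
  int n = x.size(), nb = b.size(), na = a.size();
  std::vector<double> y(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = 0; k < nb; ++k) if (i - k >= 0) acc += b[k] * x[i - k];
    for (int k = 1; k < na; ++k) if (i - k >= 0) acc -= a[k] * y[i - k];
    y[i] = acc / a[0];
  }
  return y;
}

// Zero-phase IIR filtering: reflect-pad, filter forward, reverse, filter,
// reverse, un-pad.  Equivalent to the usual forward-backward scheme.
// [[Rcpp::export]]
NumericVector filtfilt_cpp(NumericVector bb, NumericVector aa,
                           NumericVector xx) {
  int n = xx.size();
  std::vector<double> b(bb.begin(), bb.end()), a(aa.begin(), aa.end());
  int pad = std::min(n - 1, 3 * 20 * (int)std::max(b.size(), a.size()));
  std::vector<double> z;
  z.reserve(n + 2 * pad);
  for (int i = pad; i >= 1; --i) z.push_back(2 * xx[0] - xx[i]);
  for (int i = 0; i < n; ++i) z.push_back(xx[i]);
  for (int i = n - 2; i >= n - 1 - pad; --i) z.push_back(2 * xx[n - 1] - xx[i]);
  std::vector<double> y = iir_pass(b, a, z);
  std::reverse(y.begin(), y.end());
  y = iir_pass(b, a, y);
  std::reverse(y.begin(), y.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = y[i + pad];
  return out;
}

// Centred rolling mean, O(n), edges filled with the nearest full value.
// [[Rcpp::export]]
NumericVector rollmean_cpp(NumericVector x, int w) {
  int n = x.size();
  NumericVector out(n);
  if (w < 1 || n == 0) return x;
  if (w > n) w = n;
  int half = w / 2;
  double s = 0.0;
  for (int i = 0; i < w; ++i) s += x[i];
  int first = half, last = n - (w - 1 - half) - 1;
  out[first] = s / w;
  for (int c = first + 1; c <= last; ++c) {
    s += x[c + (w - 1 - half)] - x[c - half - 1];
    out[c] = s / w;
  }
  for (int i = 0; i < first; ++i) out[i] = out[first];
  for (int i = last + 1; i < n; ++i) out[i] = out[last];
  return out;
}
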