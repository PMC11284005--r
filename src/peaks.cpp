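#include <Rcpp.h>
using namespace Rcpp;

// Sequential peak acceptance with a minimum distance: among candidate
// local maxima, keep peaks at least min_dist apart, preferring the larger.
// [[Rcpp::export]]
IntegerVector pick_peaks_cpp(IntegerVector idx, NumericVector val,
                             int min_dist) {
  std::vector<int> keep;
  std::vector<double> kv;
  for (int k = 0; k < idx.size(); ++k) {
    if (!keep.empty() && idx[k] - keep.back() < min_dist) {
      if (val[k] > kv.back()) { keep.back() = idx[k]; kv.back() = val[k]; }
    } else {
      keep.push_back(idx[k]); kv.push_back(val[k]);
    }
  }
  return wrap(keep);
}

// Pan-Tompkins style adaptive signal/noise threshold pass.  Returns the
// accepted candidate indices (1-based positions into cand) and the running
// threshold at each candidate.
// [[Rcpp::export]]
List adaptive_accept_cpp(IntegerVector cand, NumericVector mwi,
                         double spki, double npki, int refr) {
  int n = cand.size();
  NumericVector thr_at(n);
  std::vector<int> acc;
  for (int k = 0; k < n; ++k) {
    int i = cand[k];
    double thr = npki + 0.25 * (spki - npki);
    thr_at[k] = thr;
    double v = mwi[i - 1];
    if (v > thr) {
      if (!acc.empty() && i - acc.back() < refr) continue;
      acc.push_back(i);
      spki = 0.125 * v + 0.875 * spki;
    } else {
      npki = 0.125 * v + 0.875 * npki;
    }
  }
  return List::create(_["accepted"] = wrap(acc), _["thr_at"] = thr_at);
}

// Refine each candidate to the largest |x| within +/- h samples (1-based).
// [[Rcpp::export]]
IntegerVector refine_r_cpp(NumericVector x, IntegerVector cand, int h) {
  int n = x.size();
  IntegerVector out(cand.size());
  for (int k = 0; k < cand.size(); ++k) {
    int lo = std::max(1, cand[k] - h), hi = std::min(n, cand[k] + h);
    int best = lo; double bv = -1.0;
    for (int i = lo; i <= hi; ++i) {
      double v = std::fabs(x[i - 1]);
      if (v > bv) { bv = v; best = i; }
    }
    out[k] = best;
  }
  return out;
}
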