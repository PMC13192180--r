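#include <Rcpp.h>
using namespace Rcpp;

// Local maxima of x (strictly greater than the previous sample, at least as
// great as the next; plateaus report their first sample). 1-based indices.
// [[Rcpp::export(name = ".localMaxima")]]
IntegerVector local_maxima(NumericVector x) {
  int n = x.size();
  std::vector<int> idx;
  int i = 1;
  while (i < n - 1) {
    if (x[i] > x[i - 1]) {
      // walk across a possible plateau
      int j = i;
      while (j < n - 1 && x[j + 1] == x[j]) ++j;
      if (j < n - 1 && x[j + 1] < x[j]) idx.push_back(i + 1);
      i = j + 1;
    } else {
      ++i;
    }
  }
  return wrap(idx);
}

// Topographic prominence of the peaks at `peaks` (1-based indices into x).
// For each peak: extend left and right until a strictly higher sample (or
// the signal edge); prominence = peak height - max(min-left, min-right).
// Matches the usual definition used by peak-finding routines.
// [[Rcpp::export(name = ".peakProminences")]]
NumericVector peak_prominences(NumericVector x, IntegerVector peaks) {
  int n = x.size(), m = peaks.size();
  NumericVector prom(m);
  for (int k = 0; k < m; ++k) {
    int p = peaks[k] - 1;
    double h = x[p];
    double minL = h, minR = h;
    for (int i = p - 1; i >= 0; --i) {
      if (x[i] > h) break;
      if (x[i] < minL) minL = x[i];
    }
    for (int i = p + 1; i < n; ++i) {
      if (x[i] > h) break;
      if (x[i] < minR) minR = x[i];
    }
    prom[k] = h - std::max(minL, minR);
  }
  return prom;
}
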