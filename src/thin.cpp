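#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen thinning of a binary matrix (0/1) down to 1-px-wide curves.
// Standard two-subiteration scheme; border pixels are left as background.
// [[Rcpp::export(name = ".thinBinary")]]
IntegerMatrix thin_binary(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix m(clone(img));
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int i = 1; i < nr - 1; ++i) {
        for (int j = 1; j < nc - 1; ++j) {
          if (m(i, j) != 1) continue;
          // 8-neighbourhood, clockwise from north: p2..p9
          int p2 = m(i - 1, j), p3 = m(i - 1, j + 1), p4 = m(i, j + 1),
              p5 = m(i + 1, j + 1), p6 = m(i + 1, j), p7 = m(i + 1, j - 1),
              p8 = m(i, j - 1), p9 = m(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        m(kill[k].first, kill[k].second) = 0;
    }
  }
  return m;
}
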