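#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labeling of a logical mask by iterative flood fill.
// Labels are assigned in raster scan order of the first-visited pixel and
// re-ordered in R by bounding-box position; connectivity is 4 or 8.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);

  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  const int nd = (connectivity == 4) ? 4 : 8;

  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc2 = idx / nr;
        for (int k = 0; k < nd; ++k) {
          int r2 = cr + dr[k], c2 = cc2 + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
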