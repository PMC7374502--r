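#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 8-connected component labelling of a binary mask by iterative flood fill.
// Returns an integer matrix of labels (0 = background, 1..k components,
// labelled in scan order).
// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const LogicalMatrix &mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * h);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % h, cc = idx / h;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int nr = cr + dr, nc = cc + dc;
            if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
            if (mask(nr, nc) && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(nr + nc * h);
            }
          }
        }
      }
    }
  }
  return lab;
}
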