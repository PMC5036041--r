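#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a logical raster.
//
// Labels are assigned in raster-scan order (row-major, top-left origin) of
// each component's first pixel, so label 1 is always the component whose
// first pixel comes earliest when reading the image like text. Connectivity
// is 4 or 8; foreground components use 8, enclosed holes 4, the usual
// complementary convention that avoids topological paradoxes.
//
// [[Rcpp::export]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  // neighbour offsets as (dr, dc)
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity;
  // row-major scan so labels follow raster order of first pixels
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Per-label pixel counts for an integer label raster (0 = background).
// [[Rcpp::export]]
IntegerVector cc_sizes(const IntegerMatrix& lab, int n_labels) {
  IntegerVector out(n_labels);
  const int n = lab.size();
  for (int i = 0; i < n; ++i) {
    int v = lab[i];
    if (v > 0 && v <= n_labels) out[v - 1]++;
  }
  return out;
}
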