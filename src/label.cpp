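#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 2D/3D logical array by flood fill.
// dims = (ny, nx, nz); first index varies fastest (R array layout).
// connectivity: 4 or 8 (in-plane, nz may be 1 or labels computed per the
// full 3D array with dz offsets suppressed), 6, 18 or 26 (3D).
// [[Rcpp::export(name = ".label_cc")]]
IntegerVector label_cc(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int ny = dims[0], nx = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  // neighbour offsets
  std::vector<int> dy, dx, dz;
  for (int oz = -1; oz <= 1; ++oz) {
    for (int ox = -1; ox <= 1; ++ox) {
      for (int oy = -1; oy <= 1; ++oy) {
        if (oy == 0 && ox == 0 && oz == 0) continue;
        int manhattan = std::abs(oy) + std::abs(ox) + std::abs(oz);
        bool keep = false;
        switch (connectivity) {
          case 4:  keep = (oz == 0 && manhattan == 1); break;
          case 8:  keep = (oz == 0); break;
          case 6:  keep = (manhattan == 1); break;
          case 18: keep = (manhattan <= 2); break;
          case 26: keep = true; break;
          default: stop("connectivity must be one of 4, 8, 6, 18, 26");
        }
        if (keep) { dy.push_back(oy); dx.push_back(ox); dz.push_back(oz); }
      }
    }
  }
  const int nn = (int)dy.size();
  const R_xlen_t plane = (R_xlen_t)ny * nx;

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++next_label;
    labels[seed] = next_label;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v / plane);
      R_xlen_t rem = v % plane;
      int x = (int)(rem / ny);
      int y = (int)(rem % ny);
      for (int k = 0; k < nn; ++k) {
        int yy = y + dy[k], xx = x + dx[k], zz = z + dz[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * plane + (R_xlen_t)xx * ny + yy;
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  labels.attr("n_components") = next_label;
  return labels;
}
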