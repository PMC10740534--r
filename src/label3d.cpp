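#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D binary mask.
// connectivity: 6 (faces) or 26 (faces, edges, corners).
// Labels are assigned in raster-scan order of the first voxel encountered,
// so the labeling is deterministic for a given mask.

// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(IntegerVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n);
  labels.attr("dim") = d;

  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back(dx);
        offs.push_back(dy);
        offs.push_back(dz);
      }

  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int cx = (int)(cur % nx);
      const int cy = (int)((cur / nx) % ny);
      const int cz = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t o = 0; o < offs.size(); o += 3) {
        const int px = cx + offs[o], py = cy + offs[o + 1], pz = cz + offs[o + 2];
        if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
        const R_xlen_t j = px + (R_xlen_t)nx * (py + (R_xlen_t)ny * pz);
        if (mask[j] != 0 && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}
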