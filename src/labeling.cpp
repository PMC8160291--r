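#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Offsets for 6- or 26-connectivity in 3D.
static void neighbour_offsets(int connectivity, std::vector<int> &dx,
                              std::vector<int> &dy, std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manhattan = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manhattan != 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Label connected components of voxels with value > 0.  When by_value is
// true, adjacency additionally requires equal voxel value (used for
// size-zone extraction); otherwise any two positive voxels are adjacent
// (used for mask post-processing).  Labels are 1..n_components in first-seen
// order; background stays 0.
// [[Rcpp::export]]
IntegerVector cc_label3d(IntegerVector vol, IntegerVector dim,
                         int connectivity, bool by_value) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector labels(vol.size(), 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nd = (int)dx.size();
  std::vector<int> stack;
  int next_label = 0;
  for (int idx = 0; idx < (int)vol.size(); ++idx) {
    if (vol[idx] <= 0 || labels[idx] != 0) continue;
    ++next_label;
    stack.clear();
    stack.push_back(idx);
    labels[idx] = next_label;
    const int value = vol[idx];
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cz = cur / (nx * ny);
      int rem = cur - cz * nx * ny;
      int cy = rem / nx;
      int cx = rem - cy * nx;
      for (int d = 0; d < nd; ++d) {
        int x = cx + dx[d], y = cy + dy[d], z = cz + dz[d];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        int nidx = x + nx * (y + ny * z);
        if (vol[nidx] <= 0 || labels[nidx] != 0) continue;
        if (by_value && vol[nidx] != value) continue;
        labels[nidx] = next_label;
        stack.push_back(nidx);
      }
    }
  }
  return labels;
}
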