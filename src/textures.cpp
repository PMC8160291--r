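#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discretized volumes are passed as integer arrays where 0 marks voxels
// outside the mask and in-mask voxels carry levels 1..ng.

static inline bool in_grid(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// Symmetric gray-level co-occurrence counts, one ng x ng slab per offset
// row; each in-mask pair (v, v+offset) increments (i,j) and (j,i).
// [[Rcpp::export]]
NumericVector glcm_counts(IntegerVector lev, IntegerVector dim, int ng,
                          IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = offsets.nrow();
  NumericVector out(ng * ng * nd, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int idx = x + nx * (y + ny * z);
        int li = lev[idx];
        if (li <= 0) continue;
        for (int d = 0; d < nd; ++d) {
          int xx = x + offsets(d, 0), yy = y + offsets(d, 1),
              zz = z + offsets(d, 2);
          if (!in_grid(xx, yy, zz, nx, ny, nz)) continue;
          int lj = lev[xx + nx * (yy + ny * zz)];
          if (lj <= 0) continue;
          out[(li - 1) + ng * (lj - 1) + ng * ng * d] += 1.0;
          out[(lj - 1) + ng * (li - 1) + ng * ng * d] += 1.0;
        }
      }
  out.attr("dim") = IntegerVector::create(ng, ng, nd);
  return out;
}

// Run-length counts: one ng x max_len slab per direction.  A run starts at
// a voxel whose predecessor along the direction is missing or differs.
// [[Rcpp::export]]
NumericVector glrlm_counts(IntegerVector lev, IntegerVector dim, int ng,
                           IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = offsets.nrow();
  int max_len = std::max(nx, std::max(ny, nz));
  // diagonal runs can span up to the shortest path across the box, but the
  // longest possible run never exceeds the largest extent
  NumericVector out(ng * max_len * nd, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int idx = x + nx * (y + ny * z);
        int li = lev[idx];
        if (li <= 0) continue;
        for (int d = 0; d < nd; ++d) {
          int ox = offsets(d, 0), oy = offsets(d, 1), oz = offsets(d, 2);
          int px = x - ox, py = y - oy, pz = z - oz;
          if (in_grid(px, py, pz, nx, ny, nz) &&
              lev[px + nx * (py + ny * pz)] == li)
            continue; // not a run start
          int len = 1;
          int cx = x + ox, cy = y + oy, cz = z + oz;
          while (in_grid(cx, cy, cz, nx, ny, nz) &&
                 lev[cx + nx * (cy + ny * cz)] == li) {
            ++len; cx += ox; cy += oy; cz += oz;
          }
          if (len > max_len) len = max_len; // cannot happen, guard anyway
          out[(li - 1) + ng * (len - 1) + ng * max_len * d] += 1.0;
        }
      }
  out.attr("dim") = IntegerVector::create(ng, max_len, nd);
  return out;
}

// Gray-level dependence counts P(g, j): j = 1 + number of 26-neighbours
// whose level differs from the centre by at most alpha (centre included so
// j >= 1).  Columns are j = 1..27.
// [[Rcpp::export]]
NumericMatrix gldm_counts(IntegerVector lev, IntegerVector dim, int ng,
                          int alpha) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int idx = x + nx * (y + ny * z);
        int li = lev[idx];
        if (li <= 0) continue;
        int dep = 0;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              if (a == 0 && b == 0 && c == 0) continue;
              int xx = x + a, yy = y + b, zz = z + c;
              if (!in_grid(xx, yy, zz, nx, ny, nz)) continue;
              int lj = lev[xx + nx * (yy + ny * zz)];
              if (lj <= 0) continue;
              if (std::abs(lj - li) <= alpha) ++dep;
            }
        out(li - 1, dep) += 1.0; // column index dep -> size dep + 1
      }
  return out;
}

// Neighbourhood gray-tone difference ingredients: for each level i, n_i =
// voxel count and s_i = sum over voxels of |i - mean(in-mask 26-neighbour
// levels)| (voxels with no in-mask neighbour contribute 0 to s).
// [[Rcpp::export]]
NumericMatrix ngtdm_stats(IntegerVector lev, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2); // columns: n_i, s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int idx = x + nx * (y + ny * z);
        int li = lev[idx];
        if (li <= 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              if (a == 0 && b == 0 && c == 0) continue;
              int xx = x + a, yy = y + b, zz = z + c;
              if (!in_grid(xx, yy, zz, nx, ny, nz)) continue;
              int lj = lev[xx + nx * (yy + ny * zz)];
              if (lj <= 0) continue;
              sum += lj; ++cnt;
            }
        out(li - 1, 0) += 1.0;
        if (cnt > 0) out(li - 1, 1) += std::abs(li - sum / cnt);
      }
  return out;
}
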