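#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Surface mesh statistics for a scalar field by marching tetrahedra.
//
// Nodes sit at voxel centres with physical coordinates index * spacing;
// the field is implicitly zero-padded so the isosurface is closed.  Every
// cell of 8 neighbouring nodes is split into six tetrahedra sharing the
// main diagonal; the uniform decomposition makes face diagonals of
// adjacent cells agree, so the triangulated surface is watertight.  Edge
// crossings are linearly interpolated (midpoints for a binary field at
// iso 0.5).  Returns c(mesh_volume, surface_area) in physical units.

struct Vec3 { double x, y, z; };

static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 vlerp(const Vec3 &a, const Vec3 &b, double t) {
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
          a.z + t * (b.z - a.z)};
}

// Isosurface crossing point on the edge between corners a (inside) and b
// (outside) by linear interpolation of the field values.
static inline Vec3 cross_pt(int a, int b, const double fv[8],
                            const Vec3 pos[8], double iso) {
  double denom = fv[b] - fv[a];
  double t = (std::fabs(denom) < 1e-12) ? 0.5 : (iso - fv[a]) / denom;
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  return vlerp(pos[a], pos[b], t);
}

// Accumulate one triangle, oriented so its normal points away from the
// inside of the surface (reference point given by `inside`).
static void add_tri(Vec3 p0, Vec3 p1, Vec3 p2, const Vec3 &inside,
                    double &vol, double &area) {
  Vec3 n = vcross(vsub(p1, p0), vsub(p2, p0));
  Vec3 centroid = {(p0.x + p1.x + p2.x) / 3 - inside.x,
                   (p0.y + p1.y + p2.y) / 3 - inside.y,
                   (p0.z + p1.z + p2.z) / 3 - inside.z};
  if (vdot(n, centroid) < 0) { Vec3 t = p1; p1 = p2; p2 = t; n = vcross(vsub(p1, p0), vsub(p2, p0)); }
  area += 0.5 * std::sqrt(vdot(n, n));
  // signed volume of tetrahedron (origin, p0, p1, p2); outward orientation
  // makes the total equal the enclosed volume
  vol += vdot(p0, vcross(p1, p2)) / 6.0;
}

// [[Rcpp::export]]
NumericVector mesh_stats_field(NumericVector field, IntegerVector dim,
                               NumericVector spacing, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner offsets, standard ordering
  static const int cx[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  static const int cy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int cz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  // six tetrahedra around the 0-6 diagonal
  static const int tets[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                                 {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  double vol = 0.0, area = 0.0;
  int val[8];
  double fv[8];
  Vec3 pos[8];
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        int nset = 0;
        for (int k = 0; k < 8; ++k) {
          int xx = x + cx[k], yy = y + cy[k], zz = z + cz[k];
          double v = 0.0;
          if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
            v = field[xx + nx * (yy + ny * zz)];
          fv[k] = v;
          val[k] = v >= iso ? 1 : 0; nset += val[k];
          pos[k] = {xx * sx, yy * sy, zz * sz};
        }
        if (nset == 0 || nset == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int inside[4], nin = 0, nout = 0;
          int ins_idx[4], out_idx[4];
          for (int k = 0; k < 4; ++k) {
            inside[k] = val[vi[k]];
            if (inside[k]) ins_idx[nin++] = vi[k]; else out_idx[nout++] = vi[k];
          }
          if (nin == 0 || nin == 4) continue;
          Vec3 ic = {0, 0, 0};
          for (int k = 0; k < nin; ++k) {
            ic.x += pos[ins_idx[k]].x; ic.y += pos[ins_idx[k]].y;
            ic.z += pos[ins_idx[k]].z;
          }
          ic.x /= nin; ic.y /= nin; ic.z /= nin;
          if (nin == 1 || nin == 3) {
            // single triangle between the lone vertex and the other three
            int lone = (nin == 1) ? ins_idx[0] : out_idx[0];
            int others[3], m = 0;
            for (int k = 0; k < 4; ++k)
              if (vi[k] != lone) others[m++] = vi[k];
            add_tri(cross_pt(lone, others[0], fv, pos, iso),
                    cross_pt(lone, others[1], fv, pos, iso),
                    cross_pt(lone, others[2], fv, pos, iso), ic, vol, area);
          } else { // nin == 2: quad from the four crossing edges
            Vec3 m00 = cross_pt(ins_idx[0], out_idx[0], fv, pos, iso);
            Vec3 m01 = cross_pt(ins_idx[0], out_idx[1], fv, pos, iso);
            Vec3 m11 = cross_pt(ins_idx[1], out_idx[1], fv, pos, iso);
            Vec3 m10 = cross_pt(ins_idx[1], out_idx[0], fv, pos, iso);
            add_tri(m00, m01, m11, ic, vol, area);
            add_tri(m00, m11, m10, ic, vol, area);
          }
        }
      }
  return NumericVector::create(vol, area);
}
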