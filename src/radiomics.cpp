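#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel grids arrive as flat vectors in R's column-major layout:
// idx = x + nx * (y + ny * z). Levels are 1..nlevels inside the ROI, 0 outside.

static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Symmetrized co-occurrence counts, one matrix per direction offset.
// [[Rcpp::export]]
List cpp_glcm_counts(IntegerVector levels, IntegerVector dims,
                     IntegerMatrix offsets, int nlevels) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nd = offsets.nrow();
  List out(nd);
  for (int d = 0; d < nd; ++d) {
    int dx = offsets(d, 0), dy = offsets(d, 1), dz = offsets(d, 2);
    NumericMatrix m(nlevels, nlevels);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[vidx(x, y, z, nx, ny)];
          if (a == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int b = levels[vidx(x2, y2, z2, nx, ny)];
          if (b == 0) continue;
          m(a - 1, b - 1) += 1.0;
          m(b - 1, a - 1) += 1.0;
        }
    out[d] = m;
  }
  return out;
}

// Maximal same-level runs per direction; matrix rows = gray level,
// columns = run length (1..maxrun).
// [[Rcpp::export]]
List cpp_glrlm_counts(IntegerVector levels, IntegerVector dims,
                      IntegerMatrix offsets, int nlevels) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nd = offsets.nrow();
  int maxrun = std::max(nx, std::max(ny, nz));
  List out(nd);
  for (int d = 0; d < nd; ++d) {
    int dx = offsets(d, 0), dy = offsets(d, 1), dz = offsets(d, 2);
    NumericMatrix m(nlevels, maxrun);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[vidx(x, y, z, nx, ny)];
          if (a == 0) continue;
          // run starts here iff predecessor is absent or different
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              levels[vidx(xp, yp, zp, nx, ny)] == a)
            continue;
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (xn >= 0 && xn < nx && yn >= 0 && yn < ny && zn >= 0 &&
                 zn < nz && levels[vidx(xn, yn, zn, nx, ny)] == a) {
            ++len;
            xn += dx; yn += dy; zn += dz;
          }
          m(a - 1, len - 1) += 1.0;
        }
    out[d] = m;
  }
  return out;
}

// 26-connected zones of equal level; returns one row (level, size) per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zlevel, zsize, stack;
  stack.reserve(256);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i0 = vidx(x, y, z, nx, ny);
        int a = levels[i0];
        if (a == 0 || seen[i0]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(i0);
        seen[i0] = 1;
        while (!stack.empty()) {
          int i = stack.back();
          stack.pop_back();
          ++size;
          int cx = i % nx, cy = (i / nx) % ny, cz = i / (nx * ny);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
                if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                    z2 >= nz)
                  continue;
                int j = vidx(x2, y2, z2, nx, ny);
                if (!seen[j] && levels[j] == a) {
                  seen[j] = 1;
                  stack.push_back(j);
                }
              }
        }
        zlevel.push_back(a);
        zsize.push_back(size);
      }
  int nzone = zlevel.size();
  IntegerMatrix out(nzone, 2);
  for (int i = 0; i < nzone; ++i) {
    out(i, 0) = zlevel[i];
    out(i, 1) = zsize[i];
  }
  return out;
}

// Dependence counts: dependence of a voxel = 1 + number of in-mask
// 26-neighbors with |level difference| <= alpha. Columns are dependence
// 1..27.
// [[Rcpp::export]]
NumericMatrix cpp_gldm_counts(IntegerVector levels, IntegerVector dims,
                              int nlevels, int alpha) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix m(nlevels, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[vidx(x, y, z, nx, ny)];
        if (a == 0) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              int b = levels[vidx(x2, y2, z2, nx, ny)];
              if (b != 0 && std::abs(b - a) <= alpha) ++dep;
            }
        m(a - 1, dep - 1) += 1.0;
      }
  return m;
}

// Neighborhood gray-tone difference: per level i, n_i = count of in-mask
// voxels of level i having at least one in-mask 26-neighbor, and
// s_i = sum over those voxels of |i - mean neighbor level|.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims,
                        int nlevels) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(nlevels, 2); // columns: n_i, s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[vidx(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              int b = levels[vidx(x2, y2, z2, nx, ny)];
              if (b != 0) {
                sum += b;
                ++cnt;
              }
            }
        if (cnt == 0) continue; // isolated voxel: no valid neighborhood
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::fabs((double)a - sum / cnt);
      }
  return out;
}

// ---- resampling -----------------------------------------------------------

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Keys cubic-convolution kernel, a = -0.5 (interpolating cubic).
static inline double keys(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.0 + t * t * (1.5 * t - 2.5);
  if (t < 2.0) return 2.0 - t * (4.0 - t * (2.5 - 0.5 * t));
  return 0.0;
}

// Resample a 3D grid. Output voxel (ox,oy,oz) samples the input at
// continuous index u_k = o_k * step_k (first voxel centers aligned).
// order 1 = trilinear, order 3 = Keys cubic; borders replicate.
// [[Rcpp::export]]
NumericVector cpp_resample3(NumericVector vol, IntegerVector dims,
                            IntegerVector outdims, NumericVector step,
                            int order) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ox = outdims[0], oy = outdims[1], oz = outdims[2];
  NumericVector out((double)ox * oy * oz);
  std::vector<double> wx(4), wy(4), wz(4);
  for (int k = 0; k < oz; ++k) {
    double uz = clampd(k * step[2], 0.0, nz - 1.0);
    for (int j = 0; j < oy; ++j) {
      double uy = clampd(j * step[1], 0.0, ny - 1.0);
      for (int i = 0; i < ox; ++i) {
        double ux = clampd(i * step[0], 0.0, nx - 1.0);
        double val = 0.0;
        if (order == 1) {
          int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
              z0 = (int)std::floor(uz);
          int x1 = clampi(x0 + 1, 0, nx - 1), y1 = clampi(y0 + 1, 0, ny - 1),
              z1 = clampi(z0 + 1, 0, nz - 1);
          double fx = ux - x0, fy = uy - y0, fz = uz - z0;
          for (int c = 0; c < 8; ++c) {
            int xx = (c & 1) ? x1 : x0;
            int yy = (c & 2) ? y1 : y0;
            int zz = (c & 4) ? z1 : z0;
            double w = ((c & 1) ? fx : 1 - fx) * ((c & 2) ? fy : 1 - fy) *
                       ((c & 4) ? fz : 1 - fz);
            val += w * vol[vidx(xx, yy, zz, nx, ny)];
          }
        } else {
          int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
              z0 = (int)std::floor(uz);
          for (int t = 0; t < 4; ++t) {
            wx[t] = keys(ux - (x0 - 1 + t));
            wy[t] = keys(uy - (y0 - 1 + t));
            wz[t] = keys(uz - (z0 - 1 + t));
          }
          for (int tz = 0; tz < 4; ++tz) {
            int zz = clampi(z0 - 1 + tz, 0, nz - 1);
            for (int ty = 0; ty < 4; ++ty) {
              int yy = clampi(y0 - 1 + ty, 0, ny - 1);
              double wyz = wy[ty] * wz[tz];
              if (wyz == 0.0) continue;
              for (int tx = 0; tx < 4; ++tx) {
                int xx = clampi(x0 - 1 + tx, 0, nx - 1);
                val += wx[tx] * wyz * vol[vidx(xx, yy, zz, nx, ny)];
              }
            }
          }
        }
        out[vidx(i, j, k, ox, oy)] = val;
      }
    }
  }
  out.attr("dim") = outdims;
  return out;
}

// ---- iso-surface mesh (marching tetrahedra) -------------------------------

struct Vec3 {
  double x, y, z;
};

static inline Vec3 vsub(Vec3 a, Vec3 b) {
  Vec3 r = {a.x - b.x, a.y - b.y, a.z - b.z};
  return r;
}
static inline Vec3 vcross(Vec3 a, Vec3 b) {
  Vec3 r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x};
  return r;
}
static inline double vdot(Vec3 a, Vec3 b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

static inline Vec3 edge_interp(Vec3 pa, Vec3 pb, double va, double vb,
                               double level) {
  double t = (level - va) / (vb - va);
  Vec3 r = {pa.x + t * (pb.x - pa.x), pa.y + t * (pb.y - pa.y),
            pa.z + t * (pb.z - pa.z)};
  return r;
}

static void add_tri(Vec3 q1, Vec3 q2, Vec3 q3, Vec3 inside_ref, double &area,
                    double &vol6) {
  Vec3 n = vcross(vsub(q2, q1), vsub(q3, q1));
  // orient the normal away from the inside of the surface
  if (vdot(n, vsub(q1, inside_ref)) < 0.0) {
    Vec3 tmp = q2;
    q2 = q3;
    q3 = tmp;
    n.x = -n.x; n.y = -n.y; n.z = -n.z;
  }
  area += 0.5 * std::sqrt(vdot(n, n));
  vol6 += vdot(q1, vcross(q2, q3));
}

static void march_tet(const Vec3 p[4], const double v[4], double level,
                      double &area, double &vol6) {
  int ins[4], outs[4], ni = 0, no = 0;
  for (int k = 0; k < 4; ++k) {
    if (v[k] > level) ins[ni++] = k; else outs[no++] = k;
  }
  if (ni == 0 || ni == 4) return;
  Vec3 ref = {0, 0, 0};
  for (int k = 0; k < ni; ++k) {
    ref.x += p[ins[k]].x; ref.y += p[ins[k]].y; ref.z += p[ins[k]].z;
  }
  ref.x /= ni; ref.y /= ni; ref.z /= ni;
  if (ni == 1) {
    int a = ins[0];
    add_tri(edge_interp(p[a], p[outs[0]], v[a], v[outs[0]], level),
            edge_interp(p[a], p[outs[1]], v[a], v[outs[1]], level),
            edge_interp(p[a], p[outs[2]], v[a], v[outs[2]], level),
            ref, area, vol6);
  } else if (ni == 3) {
    int a = outs[0];
    add_tri(edge_interp(p[ins[0]], p[a], v[ins[0]], v[a], level),
            edge_interp(p[ins[1]], p[a], v[ins[1]], v[a], level),
            edge_interp(p[ins[2]], p[a], v[ins[2]], v[a], level),
            ref, area, vol6);
  } else { // ni == 2: quad split into two triangles
    int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
    Vec3 mac = edge_interp(p[a], p[c], v[a], v[c], level);
    Vec3 mad = edge_interp(p[a], p[d], v[a], v[d], level);
    Vec3 mbd = edge_interp(p[b], p[d], v[b], v[d], level);
    Vec3 mbc = edge_interp(p[b], p[c], v[b], v[c], level);
    add_tri(mac, mad, mbd, ref, area, vol6);
    add_tri(mac, mbd, mbc, ref, area, vol6);
  }
}

// Surface area (mm^2) and enclosed volume (mm^3) of the iso-surface of a
// scalar field at `level`, by body-centered marching tetrahedra: each cell
// is split into 24 tetrahedra (cell centre, face centre, face edge) with
// centre values taken as the corner means. The symmetric decomposition
// avoids the diagonal bias of the 6-tet split, and the averaged centre
// values give first-order anti-aliasing on binary masks (flat boundaries
// mesh exactly flat). Shared faces are split identically in neighboring
// cells, so the mesh is watertight. The field must be 0 at its borders.
// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(NumericVector field, IntegerVector dims,
                                   NumericVector spacing, double level) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // corner index pairs (a,b) of the 4 edges of each of the 6 cube faces;
  // corner bit order: bit0 = x, bit1 = y, bit2 = z
  static const int faces[6][4] = {
      {0, 1, 3, 2},  // z = 0
      {4, 5, 7, 6},  // z = 1
      {0, 1, 5, 4},  // y = 0
      {2, 3, 7, 6},  // y = 1
      {0, 2, 6, 4},  // x = 0
      {1, 3, 7, 5}}; // x = 1
  double area = 0.0, vol6 = 0.0;
  double cv[8];
  Vec3 cp[8];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any_in = false, any_out = false;
        double csum = 0.0;
        for (int c = 0; c < 8; ++c) {
          int xx = x + (c & 1), yy = y + ((c >> 1) & 1), zz = z + ((c >> 2) & 1);
          cv[c] = field[vidx(xx, yy, zz, nx, ny)];
          csum += cv[c];
          cp[c].x = xx * sx;
          cp[c].y = yy * sy;
          cp[c].z = zz * sz;
          if (cv[c] > level) any_in = true; else any_out = true;
        }
        double centerv = csum / 8.0;
        if (!any_in && !(centerv > level)) continue;
        if (!any_out && (centerv > level)) continue;
        Vec3 centerp = {(x + 0.5) * sx, (y + 0.5) * sy, (z + 0.5) * sz};
        for (int f = 0; f < 6; ++f) {
          double fv = 0.0;
          Vec3 fp = {0, 0, 0};
          for (int k = 0; k < 4; ++k) {
            fv += cv[faces[f][k]];
            fp.x += cp[faces[f][k]].x;
            fp.y += cp[faces[f][k]].y;
            fp.z += cp[faces[f][k]].z;
          }
          fv /= 4.0;
          fp.x /= 4.0; fp.y /= 4.0; fp.z /= 4.0;
          for (int e = 0; e < 4; ++e) {
            int a = faces[f][e], b = faces[f][(e + 1) % 4];
            Vec3 p[4] = {cp[a], cp[b], fp, centerp};
            double v[4] = {cv[a], cv[b], fv, centerv};
            march_tet(p, v, level, area, vol6);
          }
        }
      }
  NumericVector out(2);
  out[0] = area;
  out[1] = std::fabs(vol6) / 6.0;
  return out;
}

// Largest pairwise Euclidean distance between points (rows of pts, mm).
// If drop_axis is 1..3 that coordinate is ignored (in-plane diameters);
// 0 uses all three.
// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix pts, int drop_axis) {
  int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < 3; ++k) {
        if (k + 1 == drop_axis) continue;
        double diff = pts(i, k) - pts(j, k);
        d += diff * diff;
      }
      if (d > best) best = d;
    }
  return std::sqrt(best);
}
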