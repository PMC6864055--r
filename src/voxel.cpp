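// Voxel-grid kernels for the synthetic-imaging module: partial-volume
// voxelization of a closed triangle mesh by z-column ray casting, separable
// Gaussian blur, 3D connected components, per-slice hole filling, and
// radial isosurface sampling of a (possibly anisotropic) intensity field.
// Grid convention: arrays are column-major (nx, ny, nz); voxel (i,j,k)
// (0-based) has its centre at ((i+0.5)dx, (j+0.5)dy, (k+0.5)dz) relative to
// the stack corner.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Partial-volume voxelization: each xy sub-column (nsub x nsub per voxel)
// is intersected with all triangles binned over a coarse xy grid; inside
// z-intervals (even-odd rule) are clipped against voxel z-extents exactly.
// [[Rcpp::export]]
NumericVector cpp_voxelize_mesh(const NumericMatrix& V, const IntegerMatrix& Fc,
                                double dx, double dy, double dz,
                                int nx, int ny, int nz, int nsub) {
  const int nf = Fc.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);

  // bin faces into a coarse xy grid
  const int bx = 32, by = 32;
  const double wx = nx * dx, wy = ny * dy;
  std::vector<std::vector<int>> bins(bx * by);
  for (int f = 0; f < nf; ++f) {
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int a = 0; a < 3; ++a) {
      double x = V(Fc(f, a), 0), y = V(Fc(f, a), 1);
      xmin = std::min(xmin, x); xmax = std::max(xmax, x);
      ymin = std::min(ymin, y); ymax = std::max(ymax, y);
    }
    int i0 = std::max(0, (int)std::floor(xmin / wx * bx));
    int i1 = std::min(bx - 1, (int)std::floor(xmax / wx * bx));
    int j0 = std::max(0, (int)std::floor(ymin / wy * by));
    int j1 = std::min(by - 1, (int)std::floor(ymax / wy * by));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        bins[i + bx * j].push_back(f);
  }

  const double sub = 1.0 / nsub, wsub = 1.0 / (nsub * nsub);
  std::vector<double> zc;
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      for (int si = 0; si < nsub; ++si) {
        for (int sj = 0; sj < nsub; ++sj) {
          double px = (i + (si + 0.5) * sub) * dx;
          double py = (j + (sj + 0.5) * sub) * dy;
          int bi = std::min(bx - 1, (int)(px / wx * bx));
          int bj = std::min(by - 1, (int)(py / wy * by));
          zc.clear();
          for (int f : bins[bi + bx * bj]) {
            // ray (px,py,z) along +z against triangle f (2D point-in-tri)
            double x0 = V(Fc(f, 0), 0), y0 = V(Fc(f, 0), 1), z0 = V(Fc(f, 0), 2);
            double x1 = V(Fc(f, 1), 0), y1 = V(Fc(f, 1), 1), z1 = V(Fc(f, 1), 2);
            double x2 = V(Fc(f, 2), 0), y2 = V(Fc(f, 2), 1), z2 = V(Fc(f, 2), 2);
            double d = (y1 - y2) * (x0 - x2) + (x2 - x1) * (y0 - y2);
            if (d == 0.0) continue;
            double l0 = ((y1 - y2) * (px - x2) + (x2 - x1) * (py - y2)) / d;
            double l1 = ((y2 - y0) * (px - x2) + (x0 - x2) * (py - y2)) / d;
            double l2 = 1.0 - l0 - l1;
            if (l0 < 0 || l1 < 0 || l2 < 0) continue;
            zc.push_back(l0 * z0 + l1 * z1 + l2 * z2);
          }
          if (zc.size() < 2) continue;
          std::sort(zc.begin(), zc.end());
          // inside intervals [zc[0],zc[1]], [zc[2],zc[3]], ...
          for (size_t q = 0; q + 1 < zc.size(); q += 2) {
            double za = zc[q], zb = zc[q + 1];
            int k0 = std::max(0, (int)std::floor(za / dz));
            int k1 = std::min(nz - 1, (int)std::floor(zb / dz));
            for (int k = k0; k <= k1; ++k) {
              double lo = std::max(za, k * dz), hi = std::min(zb, (k + 1) * dz);
              if (hi > lo)
                out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] +=
                  (hi - lo) / dz * wsub;
            }
          }
        }
      }
    }
  }
  return out;
}

static void blur1(std::vector<double>& buf, NumericVector& a,
                  int n, R_xlen_t stride, R_xlen_t off,
                  const std::vector<double>& ker) {
  int hw = (int)(ker.size() - 1) / 2;
  for (int i = 0; i < n; ++i) buf[i] = a[off + stride * i];
  for (int i = 0; i < n; ++i) {
    double s = 0, w = 0;
    for (int t = -hw; t <= hw; ++t) {
      int q = i + t;
      if (q < 0 || q >= n) continue;     // renormalized at borders
      s += ker[t + hw] * buf[q];
      w += ker[t + hw];
    }
    a[off + stride * i] = s / w;
  }
}

// Separable Gaussian blur with per-axis sigma in voxel units.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector a, int nx, int ny, int nz,
                             double sx, double sy, double sz) {
  NumericVector out = clone(a);
  auto kern = [](double s) {
    std::vector<double> k;
    int hw = std::max(1, (int)std::ceil(3.0 * s));
    for (int t = -hw; t <= hw; ++t)
      k.push_back(std::exp(-0.5 * t * t / (s * s)));
    return k;
  };
  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  if (sx > 0) {
    auto k = kern(sx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        blur1(buf, out, nx, 1, (R_xlen_t)nx * (y + (R_xlen_t)ny * z), k);
  }
  if (sy > 0) {
    auto k = kern(sy);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x)
        blur1(buf, out, ny, nx, x + (R_xlen_t)nx * ny * z, k);
  }
  if (sz > 0) {
    auto k = kern(sz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        blur1(buf, out, nz, (R_xlen_t)nx * ny, x + (R_xlen_t)nx * y, k);
  }
  return out;
}

// Largest 6-connected foreground component of a logical grid.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(const LogicalVector& m,
                                    int nx, int ny, int nz) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> lab(n, 0);
  int nlab = 0;
  R_xlen_t best = 0, bestsz = 0;
  std::vector<R_xlen_t> stack, comp;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    ++nlab;
    stack.assign(1, s);
    comp.clear();
    lab[s] = nlab;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      comp.push_back(v);
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      const int dxs[6] = {-1, 1, 0, 0, 0, 0};
      const int dys[6] = {0, 0, -1, 1, 0, 0};
      const int dzs[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int xx = x + dxs[t], yy = y + dys[t], zz = z + dzs[t];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (m[w] && !lab[w]) { lab[w] = nlab; stack.push_back(w); }
      }
    }
    if ((R_xlen_t)comp.size() > bestsz) { bestsz = comp.size(); best = nlab; }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (lab[s] == (int)best);
  return out;
}

// Fill holes slice-by-slice (xy planes): background connected to the slice
// border stays background, enclosed background becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_slices(const LogicalVector& m,
                                    int nx, int ny, int nz) {
  LogicalVector out = clone(m);
  std::vector<char> outside((R_xlen_t)nx * ny);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    R_xlen_t off = (R_xlen_t)nx * ny * z;
    std::fill(outside.begin(), outside.end(), 0);
    stack.clear();
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        if (x == 0 || y == 0 || x == nx - 1 || y == ny - 1) {
          int s = x + nx * y;
          if (!m[off + s] && !outside[s]) { outside[s] = 1; stack.push_back(s); }
        }
      }
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % nx, y = v / nx;
      const int dxs[4] = {-1, 1, 0, 0}, dys[4] = {0, 0, -1, 1};
      for (int t = 0; t < 4; ++t) {
        int xx = x + dxs[t], yy = y + dys[t];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
        int w = xx + nx * yy;
        if (!m[off + w] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
      }
    }
    for (R_xlen_t s = 0; s < (R_xlen_t)nx * ny; ++s)
      if (!m[off + s] && !outside[s]) out[off + s] = true;
  }
  return out;
}

static inline double trilin(const NumericVector& a, int nx, int ny, int nz,
                            double dx, double dy, double dz,
                            double x, double y, double z) {
  // voxel centres at (i+0.5)*d; clamp to the valid interpolation box
  double fx = x / dx - 0.5, fy = y / dy - 0.5, fz = z / dz - 0.5;
  fx = std::min(std::max(fx, 0.0), nx - 1.000001);
  fy = std::min(std::max(fy, 0.0), ny - 1.000001);
  fz = std::min(std::max(fz, 0.0), nz - 1.000001);
  int i = (int)fx, j = (int)fy, k = (int)fz;
  double tx = fx - i, ty = fy - j, tz = fz - k;
  double v = 0;
  for (int a2 = 0; a2 <= 1; ++a2)
    for (int b = 0; b <= 1; ++b)
      for (int c = 0; c <= 1; ++c) {
        double w = (a2 ? tx : 1 - tx) * (b ? ty : 1 - ty) * (c ? tz : 1 - tz);
        v += w * a[(i + a2) + (R_xlen_t)nx * ((j + b) + (R_xlen_t)ny * (k + c))];
      }
  return v;
}

// For each unit direction, walk outward from the centre and return the
// radius of the outermost crossing of `level` (linear interpolation between
// consecutive samples). Returns NA if the field never exceeds level.
// [[Rcpp::export]]
NumericVector cpp_ray_isosurface(const NumericVector& field,
                                 int nx, int ny, int nz,
                                 double dx, double dy, double dz,
                                 const NumericVector& center,
                                 const NumericMatrix& dirs,
                                 double level, double step, double rmax) {
  int nd = dirs.nrow();
  NumericVector out(nd);
  for (int d = 0; d < nd; ++d) {
    double ux = dirs(d, 0), uy = dirs(d, 1), uz = dirs(d, 2);
    int nstep = (int)std::ceil(rmax / step);
    double prev = trilin(field, nx, ny, nz, dx, dy, dz,
                         center[0], center[1], center[2]);
    double rc = NA_REAL;
    for (int s = 1; s <= nstep; ++s) {
      double r = s * step;
      double v = trilin(field, nx, ny, nz, dx, dy, dz,
                        center[0] + r * ux, center[1] + r * uy,
                        center[2] + r * uz);
      if ((prev >= level) != (v >= level)) {
        double t = (level - prev) / (v - prev);
        rc = r - step + t * step;
      }
      prev = v;
    }
    out[d] = rc;
  }
  return out;
}

// Count crossings of the ray from `center` along each direction with a
// triangle soup (for star-shapedness checks).
// [[Rcpp::export]]
IntegerVector cpp_ray_mesh_crossings(const NumericMatrix& V,
                                     const IntegerMatrix& Fc,
                                     const NumericVector& center,
                                     const NumericMatrix& dirs) {
  int nd = dirs.nrow(), nf = Fc.nrow();
  IntegerVector out(nd);
  for (int d = 0; d < nd; ++d) {
    double o[3] = { center[0], center[1], center[2] };
    double u[3] = { dirs(d, 0), dirs(d, 1), dirs(d, 2) };
    int cnt = 0;
    for (int f = 0; f < nf; ++f) {
      // Moller-Trumbore
      double e1[3], e2[3], p0[3];
      for (int i = 0; i < 3; ++i) {
        p0[i] = V(Fc(f, 0), i);
        e1[i] = V(Fc(f, 1), i) - p0[i];
        e2[i] = V(Fc(f, 2), i) - p0[i];
      }
      double pv[3] = { u[1] * e2[2] - u[2] * e2[1],
                       u[2] * e2[0] - u[0] * e2[2],
                       u[0] * e2[1] - u[1] * e2[0] };
      double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
      if (std::fabs(det) < 1e-12) continue;
      double tv[3] = { o[0] - p0[0], o[1] - p0[1], o[2] - p0[2] };
      double a = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) / det;
      if (a < 0 || a > 1) continue;
      double qv[3] = { tv[1] * e1[2] - tv[2] * e1[1],
                       tv[2] * e1[0] - tv[0] * e1[2],
                       tv[0] * e1[1] - tv[1] * e1[0] };
      double b = (u[0] * qv[0] + u[1] * qv[1] + u[2] * qv[2]) / det;
      if (b < 0 || a + b > 1) continue;
      double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) / det;
      if (t > 1e-12) ++cnt;
    }
    out[d] = cnt;
  }
  return out;
}
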