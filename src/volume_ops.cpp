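// Low-level 3D volume primitives shared by the registration and phantom code.
// All volumes are column-major arrays (nx, ny, nz); world coordinates are in
// millimeters with axis-aligned grids: world = origin + index * spacing,
// where `index` is zero-based and `origin` is the center of the first voxel.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---- interpolation kernels ---------------------------------------------

// Catmull-Rom cubic (interpolating) kernel, support [-2, 2].
static inline double cr_kernel(double r) {
  double a = std::fabs(r);
  if (a < 1.0) return 1.0 - a * a * (2.5 - 1.5 * a);
  if (a < 2.0) return 2.0 - a * (4.0 - a * (2.5 - 0.5 * a));
  return 0.0;
}

// Sample one volume at a continuous zero-based index position.
// interp: 0 = nearest, 1 = trilinear, 3 = tricubic (Catmull-Rom).
static double sample_vol(const double *v, int nx, int ny, int nz,
                         double cx, double cy, double cz, int interp) {
  const long sxy = (long)nx * ny;
  cx = clampd(cx, 0.0, nx - 1.0);
  cy = clampd(cy, 0.0, ny - 1.0);
  cz = clampd(cz, 0.0, nz - 1.0);
  if (interp == 0) {
    int i = (int)std::lround(cx), j = (int)std::lround(cy), k = (int)std::lround(cz);
    return v[i + (long)nx * j + sxy * k];
  }
  if (interp == 1) {
    int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
    i0 = clampi(i0, 0, nx - 2 < 0 ? 0 : nx - 2);
    j0 = clampi(j0, 0, ny - 2 < 0 ? 0 : ny - 2);
    k0 = clampi(k0, 0, nz - 2 < 0 ? 0 : nz - 2);
    double fx = cx - i0, fy = cy - j0, fz = cz - k0;
    int i1 = nx > 1 ? i0 + 1 : i0, j1 = ny > 1 ? j0 + 1 : j0, k1 = nz > 1 ? k0 + 1 : k0;
    double c000 = v[i0 + (long)nx * j0 + sxy * k0], c100 = v[i1 + (long)nx * j0 + sxy * k0];
    double c010 = v[i0 + (long)nx * j1 + sxy * k0], c110 = v[i1 + (long)nx * j1 + sxy * k0];
    double c001 = v[i0 + (long)nx * j0 + sxy * k1], c101 = v[i1 + (long)nx * j0 + sxy * k1];
    double c011 = v[i0 + (long)nx * j1 + sxy * k1], c111 = v[i1 + (long)nx * j1 + sxy * k1];
    double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
  }
  // tricubic
  int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
  double wx[4], wy[4], wz[4];
  for (int m = 0; m < 4; ++m) {
    wx[m] = cr_kernel(cx - (i0 - 1 + m));
    wy[m] = cr_kernel(cy - (j0 - 1 + m));
    wz[m] = cr_kernel(cz - (k0 - 1 + m));
  }
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) {
    int k = clampi(k0 - 1 + c, 0, nz - 1);
    double accz = 0.0;
    for (int b = 0; b < 4; ++b) {
      int j = clampi(j0 - 1 + b, 0, ny - 1);
      double accy = 0.0;
      for (int a = 0; a < 4; ++a) {
        int i = clampi(i0 - 1 + a, 0, nx - 1);
        accy += wx[a] * v[i + (long)nx * j + sxy * k];
      }
      accz += wy[b] * accy;
    }
    acc += wz[c] * accz;
  }
  return acc;
}

// [[Rcpp::export(name = ".warp_at_points")]]
NumericVector warp_at_points(NumericVector vol, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             NumericMatrix pts, int interp) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t s = 0; s < n; ++s) {
    double cx = (pts(s, 0) - origin[0]) / spacing[0];
    double cy = (pts(s, 1) - origin[1]) / spacing[1];
    double cz = (pts(s, 2) - origin[2]) / spacing[2];
    out[s] = sample_vol(v, nx, ny, nz, cx, cy, cz, interp);
  }
  return out;
}

// Trilinear evaluation of a 3-component field stored as (nx,ny,nz,3).
// [[Rcpp::export(name = ".field_at_points")]]
NumericMatrix field_at_points(NumericVector field, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 3);
  const double *v = REAL(field);
  for (R_xlen_t s = 0; s < n; ++s) {
    double cx = (pts(s, 0) - origin[0]) / spacing[0];
    double cy = (pts(s, 1) - origin[1]) / spacing[1];
    double cz = (pts(s, 2) - origin[2]) / spacing[2];
    for (int c = 0; c < 3; ++c)
      out(s, c) = sample_vol(v + (long)c * nvox, nx, ny, nz, cx, cy, cz, 1);
  }
  return out;
}

// ---- separable Gaussian smoothing ---------------------------------------

static void conv_axis(std::vector<double> &v, int nx, int ny, int nz,
                      int axis, const std::vector<double> &ker, bool renorm) {
  int r = ((int)ker.size() - 1) / 2;
  int n[3] = {nx, ny, nz};
  long stride[3] = {1, (long)nx, (long)nx * ny};
  int na = n[axis];
  long sa = stride[axis];
  int nb = axis == 0 ? ny : nx;
  int nc = axis == 2 ? ny : nz;
  long sb = axis == 0 ? stride[1] : stride[0];
  long sc = axis == 2 ? stride[1] : stride[2];
  std::vector<double> line(na);
  for (int c = 0; c < nc; ++c) {
    for (int b = 0; b < nb; ++b) {
      long base = b * sb + c * sc;
      for (int a = 0; a < na; ++a) line[a] = v[base + a * sa];
      for (int a = 0; a < na; ++a) {
        double acc = 0.0, wsum = 0.0;
        for (int m = -r; m <= r; ++m) {
          int p = a + m;
          if (p < 0 || p >= na) continue;
          acc += ker[m + r] * line[p];
          wsum += ker[m + r];
        }
        v[base + a * sa] = renorm && wsum > 0 ? acc / wsum : acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".gauss_blur3")]]
NumericVector gauss_blur3(NumericVector vol, IntegerVector dim,
                          NumericVector sigma_vox, bool renorm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> ker(2 * r + 1);
    double tot = 0.0;
    for (int m = -r; m <= r; ++m) { ker[m + r] = std::exp(-0.5 * m * m / (s * s)); tot += ker[m + r]; }
    for (auto &k : ker) k /= tot;
    conv_axis(v, nx, ny, nz, axis, ker, renorm);
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// ---- Euclidean distance transform (Felzenszwalb-Huttenlocher) -----------

static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   int n, double w2) {
  // lower envelope of parabolas; w2 = squared grid step along this axis
  std::vector<int> vtx(n);
  std::vector<double> z(n + 1);
  int k = 0;
  vtx[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    if (!std::isfinite(f[q]) && !std::isfinite(f[vtx[k]])) { continue; }
    double s;
    while (true) {
      int p = vtx[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    vtx[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = vtx[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Distance (mm) from every voxel to the nearest nonzero voxel of `mask`.
// [[Rcpp::export(name = ".edt3")]]
NumericVector edt3(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> d(nvox);
  for (long i = 0; i < nvox; ++i) d[i] = mask[i] ? 0.0 : INF;
  long stride[3] = {1, (long)nx, (long)nx * ny};
  int n[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    int na = n[axis];
    if (na < 2) continue;
    long sa = stride[axis];
    int nb = axis == 0 ? ny : nx;
    int nc = axis == 2 ? ny : nz;
    long sb = axis == 0 ? stride[1] : stride[0];
    long sc = axis == 2 ? stride[1] : stride[2];
    double w2 = spacing[axis] * spacing[axis];
    std::vector<double> line(na), out(na);
    for (int c = 0; c < nc; ++c)
      for (int b = 0; b < nb; ++b) {
        long base = b * sb + c * sc;
        bool any = false;
        for (int a = 0; a < na; ++a) { line[a] = d[base + a * sa]; if (line[a] < INF) any = true; }
        if (!any) continue;
        edt_1d(line, out, na, w2);
        for (int a = 0; a < na; ++a) d[base + a * sa] = out[a];
      }
  }
  NumericVector res(nvox);
  for (long i = 0; i < nvox; ++i) res[i] = d[i] >= 1e29 ? R_PosInf : std::sqrt(d[i]);
  res.attr("dim") = dim;
  return res;
}

// ---- watertight mesh voxelization ---------------------------------------

// Fractional voxel occupancy by parity ray casting along z on a supersampled
// (x, y) sub-grid; z coverage is exact interval arithmetic.
// [[Rcpp::export(name = ".voxelize_mesh")]]
NumericVector voxelize_mesh(NumericMatrix verts, IntegerMatrix faces,
                            IntegerVector dim, NumericVector spacing,
                            NumericVector origin, int super) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  NumericVector occ(nvox);
  int nsub = std::max(1, super);
  int ncolx = nx * nsub, ncoly = ny * nsub;
  double subx = spacing[0] / nsub, suby = spacing[1] / nsub;
  // sub-column (a, b) center: origin - spacing/2 + (a + 0.5) * sub
  double x0 = origin[0] - spacing[0] / 2.0, y0 = origin[1] - spacing[1] / 2.0;
  // deterministic sub-voxel offset avoids rays through mesh vertices/edges
  const double joff = 0.371237154;
  std::vector<std::vector<double>> cross((long)ncolx * ncoly);
  int nf = faces.nrow();
  for (int f = 0; f < nf; ++f) {
    int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
    double ax = verts(ia, 0), ay = verts(ia, 1), az = verts(ia, 2);
    double bx = verts(ib, 0), by = verts(ib, 1), bz = verts(ib, 2);
    double cx = verts(ic, 0), cy = verts(ic, 1), cz = verts(ic, 2);
    double xmin = std::min(ax, std::min(bx, cx)), xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    int a0 = clampi((int)std::floor((xmin - x0) / subx - joff), 0, ncolx - 1);
    int a1 = clampi((int)std::ceil((xmax - x0) / subx - joff), 0, ncolx - 1);
    int b0 = clampi((int)std::floor((ymin - y0) / suby - joff), 0, ncoly - 1);
    int b1 = clampi((int)std::ceil((ymax - y0) / suby - joff), 0, ncoly - 1);
    for (int b = b0; b <= b1; ++b) {
      double py = y0 + (b + 0.5 + joff * 0.5) * suby;
      for (int a = a0; a <= a1; ++a) {
        double px = x0 + (a + 0.5 + joff) * subx;
        // 2D point-in-triangle via signed areas in the xy plane
        double d1 = (bx - ax) * (py - ay) - (by - ay) * (px - ax);
        double d2 = (cx - bx) * (py - by) - (cy - by) * (px - bx);
        double d3 = (ax - cx) * (py - cy) - (ay - cy) * (px - cx);
        bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
        bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
        if (neg && pos) continue;
        double denom = d1 + d2 + d3;
        if (denom == 0.0) continue; // degenerate in projection
        double wa = d2 / denom, wb = d3 / denom, wc = d1 / denom;
        double pz = wa * az + wb * bz + wc * cz;
        cross[a + (long)ncolx * b].push_back(pz);
      }
    }
  }
  double z0 = origin[2] - spacing[2] / 2.0;
  double subw = 1.0 / ((double)nsub * nsub);
  for (int b = 0; b < ncoly; ++b) {
    int j = b / nsub;
    for (int a = 0; a < ncolx; ++a) {
      std::vector<double> &zs = cross[a + (long)ncolx * b];
      if (zs.size() < 2) continue;
      std::sort(zs.begin(), zs.end());
      int i = a / nsub;
      size_t npair = zs.size() / 2;
      for (size_t p = 0; p < npair; ++p) {
        double zin = zs[2 * p], zout = zs[2 * p + 1];
        int k0 = clampi((int)std::floor((zin - z0) / spacing[2]), 0, nz - 1);
        int k1 = clampi((int)std::floor((zout - z0) / spacing[2]), 0, nz - 1);
        for (int k = k0; k <= k1; ++k) {
          double lo = std::max(zin, z0 + k * spacing[2]);
          double hi = std::min(zout, z0 + (k + 1) * spacing[2]);
          if (hi > lo)
            occ[i + (long)nx * j + (long)nx * ny * k] += (hi - lo) / spacing[2] * subw;
        }
      }
    }
  }
  for (long i = 0; i < nvox; ++i) occ[i] = clampd(occ[i], 0.0, 1.0);
  occ.attr("dim") = dim;
  return occ;
}

// ---- displacement-field utilities ---------------------------------------

// Fixed-point inversion: find v with v(y) = -u(y + v(y)).
// [[Rcpp::export(name = ".invert_field")]]
NumericVector invert_field(NumericVector field, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           int iters) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  NumericVector out(nvox * 3);
  const double *u = REAL(field);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long idx = i + (long)nx * j + (long)nx * ny * k;
        double wx = origin[0] + i * spacing[0];
        double wy = origin[1] + j * spacing[1];
        double wz = origin[2] + k * spacing[2];
        double vx = 0, vy = 0, vz = 0;
        for (int it = 0; it < iters; ++it) {
          double cx = (wx + vx - origin[0]) / spacing[0];
          double cy = (wy + vy - origin[1]) / spacing[1];
          double cz = (wz + vz - origin[2]) / spacing[2];
          vx = -sample_vol(u, nx, ny, nz, cx, cy, cz, 1);
          vy = -sample_vol(u + nvox, nx, ny, nz, cx, cy, cz, 1);
          vz = -sample_vol(u + 2 * nvox, nx, ny, nz, cx, cy, cz, 1);
        }
        out[idx] = vx; out[idx + nvox] = vy; out[idx + 2 * nvox] = vz;
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// Jacobian determinant of x + u(x) by central differences.
// [[Rcpp::export(name = ".jacobian_det")]]
NumericVector jacobian_det(NumericVector field, IntegerVector dim,
                           NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  const double *u = REAL(field);
  NumericVector out(nvox);
  long stride[3] = {1, (long)nx, (long)nx * ny};
  int n[3] = {nx, ny, nz};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long idx = i + (long)nx * j + (long)nx * ny * k;
        int pos[3] = {i, j, k};
        double J[3][3];
        for (int a = 0; a < 3; ++a) {     // derivative axis
          int lo = std::max(pos[a] - 1, 0), hi = std::min(pos[a] + 1, n[a] - 1);
          double h = (hi - lo) * spacing[a];
          for (int c = 0; c < 3; ++c) {   // component
            double vhi = u[idx + (hi - pos[a]) * stride[a] + (long)c * nvox];
            double vlo = u[idx + (lo - pos[a]) * stride[a] + (long)c * nvox];
            J[c][a] = (h > 0 ? (vhi - vlo) / h : 0.0) + (c == a ? 1.0 : 0.0);
          }
        }
        out[idx] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
                 - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
                 + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  out.attr("dim") = dim;
  return out;
}

// Central-difference spatial gradient of a volume (per mm), 3 output arrays.
// [[Rcpp::export(name = ".gradient_volume")]]
NumericVector gradient_volume(NumericVector vol, IntegerVector dim,
                              NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  const double *v = REAL(vol);
  NumericVector out(nvox * 3);
  long stride[3] = {1, (long)nx, (long)nx * ny};
  int n[3] = {nx, ny, nz};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long idx = i + (long)nx * j + (long)nx * ny * k;
        int pos[3] = {i, j, k};
        for (int a = 0; a < 3; ++a) {
          int lo = std::max(pos[a] - 1, 0), hi = std::min(pos[a] + 1, n[a] - 1);
          double h = (hi - lo) * spacing[a];
          out[idx + (long)a * nvox] =
            h > 0 ? (v[idx + (hi - pos[a]) * stride[a]] - v[idx + (lo - pos[a]) * stride[a]]) / h : 0.0;
        }
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// ---- centerline helpers --------------------------------------------------

// Dijkstra over the 26-connected voxel graph restricted to `mask`.
// Edge cost: euclidean step length times the mean of the node weights.
// Returns list(dist = distances from `from`, far = index of farthest reachable
// voxel (1-based), path = 1-based voxel indices from `from` to `to` (if to>0)).
// [[Rcpp::export(name = ".mask_dijkstra")]]
List mask_dijkstra(LogicalVector mask, IntegerVector dim, NumericVector spacing,
                   NumericVector weight, int from, int to) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  std::vector<double> dist(nvox, std::numeric_limits<double>::infinity());
  std::vector<long> prev(nvox, -1);
  typedef std::pair<double, long> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  long src = from - 1;
  dist[src] = 0.0;
  pq.push(QE(0.0, src));
  int di[26], dj[26], dk[26];
  double dl[26];
  int nn = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (!a && !b && !c) continue;
        di[nn] = a; dj[nn] = b; dk[nn] = c;
        dl[nn] = std::sqrt(a * a * spacing[0] * spacing[0] +
                           b * b * spacing[1] * spacing[1] +
                           c * c * spacing[2] * spacing[2]);
        ++nn;
      }
  double far_d = -1.0;
  long far_i = src;
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    long u = top.second;
    if (top.first > dist[u]) continue;
    if (dist[u] > far_d) { far_d = dist[u]; far_i = u; }
    if (to > 0 && u == to - 1) break;
    int i = (int)(u % nx), j = (int)((u / nx) % ny), k = (int)(u / ((long)nx * ny));
    for (int m = 0; m < nn; ++m) {
      int i2 = i + di[m], j2 = j + dj[m], k2 = k + dk[m];
      if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz) continue;
      long v2 = i2 + (long)nx * j2 + (long)nx * ny * k2;
      if (!mask[v2]) continue;
      double w = dl[m] * 0.5 * (weight[u] + weight[v2]);
      if (dist[u] + w < dist[v2]) {
        dist[v2] = dist[u] + w;
        prev[v2] = u;
        pq.push(QE(dist[v2], v2));
      }
    }
  }
  std::vector<double> path;
  if (to > 0) {
    long cur = to - 1;
    while (cur >= 0) { path.push_back((double)(cur + 1)); cur = prev[cur]; }
    std::reverse(path.begin(), path.end());
  }
  return List::create(_["dist"] = NumericVector(dist.begin(), dist.end()),
                      _["far"] = (double)(far_i + 1),
                      _["path"] = NumericVector(path.begin(), path.end()));
}
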