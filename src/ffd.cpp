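// Cubic B-spline free-form deformation (FFD): evaluation, and the analytic
// cost/gradient used by the deformable registration stages.
//
// Control lattice: component c of the displacement at world point x is
//   u_c(x) = sum_{abc} coef[idx(a,b,c) + c*ncp] B(tx-a) B(ty-b) B(tz-c)
// with t = (x - gorig) / gspc. The lattice must cover every evaluation point
// with a full 4x4x4 support (guaranteed by the R-side grid construction).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void bspl_w(double t, double *w) {
  double t2 = t * t, t3 = t2 * t, omt = 1.0 - t;
  w[0] = omt * omt * omt / 6.0;
  w[1] = (3.0 * t3 - 6.0 * t2 + 4.0) / 6.0;
  w[2] = (-3.0 * t3 + 3.0 * t2 + 3.0 * t + 1.0) / 6.0;
  w[3] = t3 / 6.0;
}

static inline void bspl_dw(double t, double *w) {
  double t2 = t * t, omt = 1.0 - t;
  w[0] = -omt * omt / 2.0;
  w[1] = 1.5 * t2 - 2.0 * t;
  w[2] = -1.5 * t2 + t + 0.5;
  w[3] = t2 / 2.0;
}

static inline void bspl_ddw(double t, double *w) {
  w[0] = 1.0 - t;
  w[1] = 3.0 * t - 2.0;
  w[2] = 1.0 - 3.0 * t;
  w[3] = t;
}

struct FFDGrid {
  double gorig[3], gspc[3];
  int nc[3];
  long ncp;
};

static inline bool grid_locate(const FFDGrid &g, const double *x,
                               int *base, double *t) {
  for (int a = 0; a < 3; ++a) {
    double s = (x[a] - g.gorig[a]) / g.gspc[a];
    int b = (int)std::floor(s);
    t[a] = s - b;
    base[a] = b - 1;
    if (base[a] < 0 || base[a] + 3 >= g.nc[a]) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".ffd_eval_points")]]
NumericMatrix ffd_eval_points(NumericVector coef, NumericVector gorig,
                              NumericVector gspc, IntegerVector nc,
                              NumericMatrix pts) {
  FFDGrid g;
  for (int a = 0; a < 3; ++a) { g.gorig[a] = gorig[a]; g.gspc[a] = gspc[a]; g.nc[a] = nc[a]; }
  g.ncp = (long)nc[0] * nc[1] * nc[2];
  const double *cf = REAL(coef);
  R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 3);
  double wx[4], wy[4], wz[4], x[3], t[3];
  int base[3];
  for (R_xlen_t s = 0; s < n; ++s) {
    x[0] = pts(s, 0); x[1] = pts(s, 1); x[2] = pts(s, 2);
    if (!grid_locate(g, x, base, t))
      stop("point outside the B-spline lattice support");
    bspl_w(t[0], wx); bspl_w(t[1], wy); bspl_w(t[2], wz);
    double u[3] = {0, 0, 0};
    for (int c = 0; c < 4; ++c) {
      long kz = (long)(base[2] + c) * nc[0] * nc[1];
      for (int b = 0; b < 4; ++b) {
        long ky = kz + (long)(base[1] + b) * nc[0];
        double wyz = wy[b] * wz[c];
        for (int a = 0; a < 4; ++a) {
          long idx = ky + base[0] + a;
          double w = wx[a] * wyz;
          u[0] += cf[idx] * w;
          u[1] += cf[idx + g.ncp] * w;
          u[2] += cf[idx + 2 * g.ncp] * w;
        }
      }
    }
    out(s, 0) = u[0]; out(s, 1) = u[1]; out(s, 2) = u[2];
  }
  return out;
}

// ---- shared sampling helpers --------------------------------------------

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// trilinear sample of one volume at continuous index
static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double cx, double cy, double cz) {
  cx = clampd(cx, 0.0, nx - 1.0);
  cy = clampd(cy, 0.0, ny - 1.0);
  cz = clampd(cz, 0.0, nz - 1.0);
  int i0 = std::min((int)std::floor(cx), nx - 2 > 0 ? nx - 2 : 0);
  int j0 = std::min((int)std::floor(cy), ny - 2 > 0 ? ny - 2 : 0);
  int k0 = std::min((int)std::floor(cz), nz - 2 > 0 ? nz - 2 : 0);
  double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  long sxy = (long)nx * ny;
  int i1 = nx > 1 ? i0 + 1 : i0, j1 = ny > 1 ? j0 + 1 : j0, k1 = nz > 1 ? k0 + 1 : k0;
  double c00 = v[i0 + (long)nx * j0 + sxy * k0] * (1 - fx) + v[i1 + (long)nx * j0 + sxy * k0] * fx;
  double c10 = v[i0 + (long)nx * j1 + sxy * k0] * (1 - fx) + v[i1 + (long)nx * j1 + sxy * k0] * fx;
  double c01 = v[i0 + (long)nx * j0 + sxy * k1] * (1 - fx) + v[i1 + (long)nx * j0 + sxy * k1] * fx;
  double c11 = v[i0 + (long)nx * j1 + sxy * k1] * (1 - fx) + v[i1 + (long)nx * j1 + sxy * k1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// cubic B-spline Parzen kernel and derivative (support (-2, 2))
static inline double parzen3(double r) {
  double a = std::fabs(r);
  if (a < 1.0) return (4.0 - 6.0 * a * a + 3.0 * a * a * a) / 6.0;
  if (a < 2.0) { double b = 2.0 - a; return b * b * b / 6.0; }
  return 0.0;
}

static inline double parzen3_d(double r) {
  double a = std::fabs(r), s = r < 0 ? -1.0 : 1.0;
  if (a < 1.0) return s * (-2.0 * a + 1.5 * a * a);
  if (a < 2.0) { double b = 2.0 - a; return s * (-0.5 * b * b); }
  return 0.0;
}

// Plain Parzen-window mutual information (nats) between two sample vectors.
// Linear window on the first variable, cubic B-spline window on the second;
// identical binning to the registration metric.
// [[Rcpp::export(name = ".mi_parzen")]]
double mi_parzen(NumericVector f, NumericVector m, int nbins,
                 double fmin, double fmax, double mmin, double mmax) {
  int nb = nbins;
  std::vector<double> H((long)nb * nb, 0.0);
  double fw = (fmax - fmin) / (nb - 1), mw = (mmax - mmin) / (nb - 1);
  if (fw <= 0 || mw <= 0) stop("degenerate intensity range");
  R_xlen_t n = f.size();
  for (R_xlen_t s = 0; s < n; ++s) {
    double bf = clampd((f[s] - fmin) / fw, 0.0, nb - 1.0);
    double bm = clampd((m[s] - mmin) / mw, 1.0, nb - 2.000001);
    int k0 = std::min((int)std::floor(bf), nb - 2);
    double wk1 = bf - k0;
    int l0 = (int)std::floor(bm) - 1;
    for (int dk = 0; dk < 2; ++dk) {
      double wk = dk == 0 ? 1.0 - wk1 : wk1;
      if (wk == 0.0) continue;
      for (int dl = 0; dl < 4; ++dl)
        H[(k0 + dk) + (long)nb * (l0 + dl)] += wk * parzen3(bm - (l0 + dl));
    }
  }
  double tot = 0.0;
  for (double h : H) tot += h;
  std::vector<double> pf(nb, 0.0), pm(nb, 0.0);
  for (int l = 0; l < nb; ++l)
    for (int k = 0; k < nb; ++k) {
      double p = H[k + (long)nb * l] / tot;
      pf[k] += p; pm[l] += p;
    }
  double mi = 0.0;
  for (int l = 0; l < nb; ++l)
    for (int k = 0; k < nb; ++k) {
      double p = H[k + (long)nb * l] / tot;
      if (p > 1e-12) mi += p * std::log(p / (pf[k] * pm[l] + 1e-300));
    }
  return mi;
}

// ---- registration cost + gradient ----------------------------------------
//
// cost = similarity + beWeight * BE + rigWeight * RIG
// similarity: metric 0 = mean squared difference, 1 = negative MI (nats).
// BE is evaluated on its own sample set (mean squared Frobenius norm of the
// displacement Hessian); RIG on the rigidity sample set (LN + OC + PC).
// [[Rcpp::export(name = ".ffd_cost_grad")]]
List ffd_cost_grad(NumericVector coef, NumericVector gorig, NumericVector gspc,
                   IntegerVector nc, NumericMatrix simPts, NumericVector fixedVals,
                   NumericVector mov, IntegerVector mdim, NumericVector mspc,
                   NumericVector morig, NumericVector movGrad,
                   int metric, int nbins, double fmin, double fmax,
                   double mmin, double mmax,
                   NumericMatrix bePts, double beWeight,
                   NumericMatrix rigPts, double rigWeight,
                   NumericMatrix baseDisp) {
  FFDGrid g;
  for (int a = 0; a < 3; ++a) { g.gorig[a] = gorig[a]; g.gspc[a] = gspc[a]; g.nc[a] = nc[a]; }
  g.ncp = (long)nc[0] * nc[1] * nc[2];
  const double *cf = REAL(coef);
  const double *mv = REAL(mov);
  const double *mg = REAL(movGrad);
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  long nvoxm = (long)nx * ny * nz;
  R_xlen_t ns = simPts.nrow();
  NumericVector grad(3 * g.ncp);
  double *gr = REAL(grad);

  std::vector<double> msamp(ns), gsamp(3 * ns);
  double wx[4], wy[4], wz[4], x[3], t[3];
  int base[3];
  bool hasBase = baseDisp.nrow() == ns;

  // ---- pass A: sample moving image at warped points ----
  for (R_xlen_t s = 0; s < ns; ++s) {
    x[0] = simPts(s, 0); x[1] = simPts(s, 1); x[2] = simPts(s, 2);
    if (!grid_locate(g, x, base, t)) stop("similarity sample outside lattice");
    bspl_w(t[0], wx); bspl_w(t[1], wy); bspl_w(t[2], wz);
    double u[3] = {0, 0, 0};
    if (hasBase) { u[0] = baseDisp(s, 0); u[1] = baseDisp(s, 1); u[2] = baseDisp(s, 2); }
    for (int c = 0; c < 4; ++c) {
      long kz = (long)(base[2] + c) * nc[0] * nc[1];
      for (int b = 0; b < 4; ++b) {
        long ky = kz + (long)(base[1] + b) * nc[0];
        double wyz = wy[b] * wz[c];
        for (int a = 0; a < 4; ++a) {
          long idx = ky + base[0] + a;
          double w = wx[a] * wyz;
          u[0] += cf[idx] * w; u[1] += cf[idx + g.ncp] * w; u[2] += cf[idx + 2 * g.ncp] * w;
        }
      }
    }
    double cx = (x[0] + u[0] - morig[0]) / mspc[0];
    double cy = (x[1] + u[1] - morig[1]) / mspc[1];
    double cz = (x[2] + u[2] - morig[2]) / mspc[2];
    msamp[s] = tri_sample(mv, nx, ny, nz, cx, cy, cz);
    gsamp[3 * s]     = tri_sample(mg, nx, ny, nz, cx, cy, cz);
    gsamp[3 * s + 1] = tri_sample(mg + nvoxm, nx, ny, nz, cx, cy, cz);
    gsamp[3 * s + 2] = tri_sample(mg + 2 * nvoxm, nx, ny, nz, cx, cy, cz);
  }

  // ---- similarity value and dSim/dm per sample ----
  double sim = 0.0;
  std::vector<double> dVdm(ns, 0.0);
  if (metric == 0) {
    for (R_xlen_t s = 0; s < ns; ++s) {
      double r = msamp[s] - fixedVals[s];
      sim += r * r;
      dVdm[s] = 2.0 * r / ns;
    }
    sim /= ns;
  } else {
    int nb = nbins;
    double fw = (fmax - fmin) / (nb - 1), mw = (mmax - mmin) / (nb - 1);
    std::vector<double> H((long)nb * nb, 0.0);
    std::vector<double> bfv(ns), bmv(ns);
    for (R_xlen_t s = 0; s < ns; ++s) {
      bfv[s] = clampd((fixedVals[s] - fmin) / fw, 0.0, nb - 1.0);
      bmv[s] = clampd((msamp[s] - mmin) / mw, 1.0, nb - 2.000001);
      int k0 = std::min((int)std::floor(bfv[s]), nb - 2);
      double wk1 = bfv[s] - k0;
      int l0 = (int)std::floor(bmv[s]) - 1;
      for (int dk = 0; dk < 2; ++dk) {
        double wk = dk == 0 ? 1.0 - wk1 : wk1;
        if (wk == 0.0) continue;
        for (int dl = 0; dl < 4; ++dl)
          H[(k0 + dk) + (long)nb * (l0 + dl)] += wk * parzen3(bmv[s] - (l0 + dl));
      }
    }
    double tot = 0.0;
    for (double h : H) tot += h;
    std::vector<double> pf(nb, 0.0), pm(nb, 0.0);
    for (int l = 0; l < nb; ++l)
      for (int k = 0; k < nb; ++k) { double p = H[k + (long)nb * l] / tot; pf[k] += p; pm[l] += p; }
    std::vector<double> lg((long)nb * nb, 0.0);
    double mi = 0.0;
    for (int l = 0; l < nb; ++l)
      for (int k = 0; k < nb; ++k) {
        double p = H[k + (long)nb * l] / tot;
        if (p > 1e-12) {
          lg[k + (long)nb * l] = std::log(p / (pm[l] + 1e-300));
          mi += p * std::log(p / (pf[k] * pm[l] + 1e-300));
        }
      }
    sim = -mi;
    for (R_xlen_t s = 0; s < ns; ++s) {
      int k0 = std::min((int)std::floor(bfv[s]), nb - 2);
      double wk1 = bfv[s] - k0;
      int l0 = (int)std::floor(bmv[s]) - 1;
      double acc = 0.0;
      for (int dk = 0; dk < 2; ++dk) {
        double wk = dk == 0 ? 1.0 - wk1 : wk1;
        if (wk == 0.0) continue;
        for (int dl = 0; dl < 4; ++dl)
          acc += wk * parzen3_d(bmv[s] - (l0 + dl)) * lg[(k0 + dk) + (long)nb * (l0 + dl)];
      }
      dVdm[s] = -acc / (tot * mw);   // d(-MI)/dm
    }
  }

  // ---- pass B: scatter similarity gradient ----
  for (R_xlen_t s = 0; s < ns; ++s) {
    if (dVdm[s] == 0.0) continue;
    x[0] = simPts(s, 0); x[1] = simPts(s, 1); x[2] = simPts(s, 2);
    grid_locate(g, x, base, t);
    bspl_w(t[0], wx); bspl_w(t[1], wy); bspl_w(t[2], wz);
    double f0 = dVdm[s] * gsamp[3 * s], f1 = dVdm[s] * gsamp[3 * s + 1], f2 = dVdm[s] * gsamp[3 * s + 2];
    for (int c = 0; c < 4; ++c) {
      long kz = (long)(base[2] + c) * nc[0] * nc[1];
      for (int b = 0; b < 4; ++b) {
        long ky = kz + (long)(base[1] + b) * nc[0];
        double wyz = wy[b] * wz[c];
        for (int a = 0; a < 4; ++a) {
          long idx = ky + base[0] + a;
          double w = wx[a] * wyz;
          gr[idx] += f0 * w; gr[idx + g.ncp] += f1 * w; gr[idx + 2 * g.ncp] += f2 * w;
        }
      }
    }
  }

  // ---- bending-energy penalty ----
  double be = 0.0;
  R_xlen_t nbe = bePts.nrow();
  if (beWeight > 0 && nbe > 0) {
    double dwx[4], dwy[4], dwz[4], ddx[4], ddy[4], ddz[4];
    for (R_xlen_t s = 0; s < nbe; ++s) {
      x[0] = bePts(s, 0); x[1] = bePts(s, 1); x[2] = bePts(s, 2);
      if (!grid_locate(g, x, base, t)) stop("bending sample outside lattice");
      bspl_w(t[0], wx); bspl_w(t[1], wy); bspl_w(t[2], wz);
      bspl_dw(t[0], dwx); bspl_dw(t[1], dwy); bspl_dw(t[2], dwz);
      bspl_ddw(t[0], ddx); bspl_ddw(t[1], ddy); bspl_ddw(t[2], ddz);
      // Hessian H[comp][ab] for ab in {xx,yy,zz,xy,xz,yz}
      double Hm[3][6] = {{0}};
      for (int c = 0; c < 4; ++c) {
        long kz = (long)(base[2] + c) * nc[0] * nc[1];
        for (int b = 0; b < 4; ++b) {
          long ky = kz + (long)(base[1] + b) * nc[0];
          for (int a = 0; a < 4; ++a) {
            long idx = ky + base[0] + a;
            double wxx = ddx[a] * wy[b] * wz[c] / (g.gspc[0] * g.gspc[0]);
            double wyy = wx[a] * ddy[b] * wz[c] / (g.gspc[1] * g.gspc[1]);
            double wzz = wx[a] * wy[b] * ddz[c] / (g.gspc[2] * g.gspc[2]);
            double wxy = dwx[a] * dwy[b] * wz[c] / (g.gspc[0] * g.gspc[1]);
            double wxz = dwx[a] * wy[b] * dwz[c] / (g.gspc[0] * g.gspc[2]);
            double wyz2 = wx[a] * dwy[b] * dwz[c] / (g.gspc[1] * g.gspc[2]);
            for (int cc = 0; cc < 3; ++cc) {
              double cv = cf[idx + (long)cc * g.ncp];
              Hm[cc][0] += cv * wxx; Hm[cc][1] += cv * wyy; Hm[cc][2] += cv * wzz;
              Hm[cc][3] += cv * wxy; Hm[cc][4] += cv * wxz; Hm[cc][5] += cv * wyz2;
            }
          }
        }
      }
      double mult[6] = {1, 1, 1, 2, 2, 2};  // mixed terms appear twice in the Hessian
      for (int cc = 0; cc < 3; ++cc)
        for (int q = 0; q < 6; ++q) be += mult[q] * Hm[cc][q] * Hm[cc][q];
      // gradient scatter
      double fac = beWeight * 2.0 / nbe;
      for (int c = 0; c < 4; ++c) {
        long kz = (long)(base[2] + c) * nc[0] * nc[1];
        for (int b = 0; b < 4; ++b) {
          long ky = kz + (long)(base[1] + b) * nc[0];
          for (int a = 0; a < 4; ++a) {
            long idx = ky + base[0] + a;
            double wq[6];
            wq[0] = ddx[a] * wy[b] * wz[c] / (g.gspc[0] * g.gspc[0]);
            wq[1] = wx[a] * ddy[b] * wz[c] / (g.gspc[1] * g.gspc[1]);
            wq[2] = wx[a] * wy[b] * ddz[c] / (g.gspc[2] * g.gspc[2]);
            wq[3] = dwx[a] * dwy[b] * wz[c] / (g.gspc[0] * g.gspc[1]);
            wq[4] = dwx[a] * wy[b] * dwz[c] / (g.gspc[0] * g.gspc[2]);
            wq[5] = wx[a] * dwy[b] * dwz[c] / (g.gspc[1] * g.gspc[2]);
            for (int cc = 0; cc < 3; ++cc) {
              double acc = 0.0;
              acc += Hm[cc][0] * wq[0] + Hm[cc][1] * wq[1] + Hm[cc][2] * wq[2];
              acc += 2.0 * (Hm[cc][3] * wq[3] + Hm[cc][4] * wq[4] + Hm[cc][5] * wq[5]);
              gr[idx + (long)cc * g.ncp] += fac * acc;
            }
          }
        }
      }
    }
    be /= nbe;
  }

  // ---- rigidity penalty (LN + OC + PC) ----
  double rig = 0.0;
  R_xlen_t nrg = rigPts.nrow();
  if (rigWeight > 0 && nrg > 0) {
    double dwx[4], dwy[4], dwz[4], ddx[4], ddy[4], ddz[4];
    for (R_xlen_t s = 0; s < nrg; ++s) {
      x[0] = rigPts(s, 0); x[1] = rigPts(s, 1); x[2] = rigPts(s, 2);
      if (!grid_locate(g, x, base, t)) stop("rigidity sample outside lattice");
      bspl_w(t[0], wx); bspl_w(t[1], wy); bspl_w(t[2], wz);
      bspl_dw(t[0], dwx); bspl_dw(t[1], dwy); bspl_dw(t[2], dwz);
      bspl_ddw(t[0], ddx); bspl_ddw(t[1], ddy); bspl_ddw(t[2], ddz);
      double J[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
      double Hm[3][6] = {{0}};
      for (int c = 0; c < 4; ++c) {
        long kz = (long)(base[2] + c) * nc[0] * nc[1];
        for (int b = 0; b < 4; ++b) {
          long ky = kz + (long)(base[1] + b) * nc[0];
          for (int a = 0; a < 4; ++a) {
            long idx = ky + base[0] + a;
            double dwa[3] = {dwx[a] * wy[b] * wz[c] / g.gspc[0],
                             wx[a] * dwy[b] * wz[c] / g.gspc[1],
                             wx[a] * wy[b] * dwz[c] / g.gspc[2]};
            double wq[6];
            wq[0] = ddx[a] * wy[b] * wz[c] / (g.gspc[0] * g.gspc[0]);
            wq[1] = wx[a] * ddy[b] * wz[c] / (g.gspc[1] * g.gspc[1]);
            wq[2] = wx[a] * wy[b] * ddz[c] / (g.gspc[2] * g.gspc[2]);
            wq[3] = dwx[a] * dwy[b] * wz[c] / (g.gspc[0] * g.gspc[1]);
            wq[4] = dwx[a] * wy[b] * dwz[c] / (g.gspc[0] * g.gspc[2]);
            wq[5] = wx[a] * dwy[b] * dwz[c] / (g.gspc[1] * g.gspc[2]);
            for (int cc = 0; cc < 3; ++cc) {
              double cv = cf[idx + (long)cc * g.ncp];
              J[cc][0] += cv * dwa[0]; J[cc][1] += cv * dwa[1]; J[cc][2] += cv * dwa[2];
              for (int q = 0; q < 6; ++q) Hm[cc][q] += cv * wq[q];
            }
          }
        }
      }
      // LN: squared second derivatives (full Hessian Frobenius norm)
      double mult[6] = {1, 1, 1, 2, 2, 2};
      double ln = 0.0;
      for (int cc = 0; cc < 3; ++cc)
        for (int q = 0; q < 6; ++q) ln += mult[q] * Hm[cc][q] * Hm[cc][q];
      // OC: || J^T J - I ||_F^2
      double A[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double v = 0.0;
          for (int k = 0; k < 3; ++k) v += J[k][i] * J[k][j];
          A[i][j] = v - (i == j ? 1.0 : 0.0);
        }
      double oc = 0.0;
      for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) oc += A[i][j] * A[i][j];
      // PC: (det J - 1)^2
      double det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
                 - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
                 + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      double pc = (det - 1.0) * (det - 1.0);
      rig += ln + oc + pc;
      // dOC/dJ = 4 J (J^T J - I); dPC/dJ = 2 (det - 1) cof(J)
      double dJ[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double v = 0.0;
          for (int k = 0; k < 3; ++k) v += J[i][k] * A[k][j];
          dJ[i][j] = 4.0 * v;
        }
      double cofm[3][3];
      cofm[0][0] = J[1][1] * J[2][2] - J[1][2] * J[2][1];
      cofm[0][1] = J[1][2] * J[2][0] - J[1][0] * J[2][2];
      cofm[0][2] = J[1][0] * J[2][1] - J[1][1] * J[2][0];
      cofm[1][0] = J[0][2] * J[2][1] - J[0][1] * J[2][2];
      cofm[1][1] = J[0][0] * J[2][2] - J[0][2] * J[2][0];
      cofm[1][2] = J[0][1] * J[2][0] - J[0][0] * J[2][1];
      cofm[2][0] = J[0][1] * J[1][2] - J[0][2] * J[1][1];
      cofm[2][1] = J[0][2] * J[1][0] - J[0][0] * J[1][2];
      cofm[2][2] = J[0][0] * J[1][1] - J[0][1] * J[1][0];
      double dpc = 2.0 * (det - 1.0);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) dJ[i][j] += dpc * cofm[i][j];
      double fac = rigWeight / nrg;
      for (int c = 0; c < 4; ++c) {
        long kz = (long)(base[2] + c) * nc[0] * nc[1];
        for (int b = 0; b < 4; ++b) {
          long ky = kz + (long)(base[1] + b) * nc[0];
          for (int a = 0; a < 4; ++a) {
            long idx = ky + base[0] + a;
            double dwa[3] = {dwx[a] * wy[b] * wz[c] / g.gspc[0],
                             wx[a] * dwy[b] * wz[c] / g.gspc[1],
                             wx[a] * wy[b] * dwz[c] / g.gspc[2]};
            double wq[6];
            wq[0] = ddx[a] * wy[b] * wz[c] / (g.gspc[0] * g.gspc[0]);
            wq[1] = wx[a] * ddy[b] * wz[c] / (g.gspc[1] * g.gspc[1]);
            wq[2] = wx[a] * wy[b] * ddz[c] / (g.gspc[2] * g.gspc[2]);
            wq[3] = dwx[a] * dwy[b] * wz[c] / (g.gspc[0] * g.gspc[1]);
            wq[4] = dwx[a] * wy[b] * dwz[c] / (g.gspc[0] * g.gspc[2]);
            wq[5] = wx[a] * dwy[b] * dwz[c] / (g.gspc[1] * g.gspc[2]);
            for (int cc = 0; cc < 3; ++cc) {
              double acc = dJ[cc][0] * dwa[0] + dJ[cc][1] * dwa[1] + dJ[cc][2] * dwa[2];
              acc += 2.0 * (Hm[cc][0] * wq[0] + Hm[cc][1] * wq[1] + Hm[cc][2] * wq[2]);
              acc += 4.0 * (Hm[cc][3] * wq[3] + Hm[cc][4] * wq[4] + Hm[cc][5] * wq[5]);
              gr[idx + (long)cc * g.ncp] += fac * acc;
            }
          }
        }
      }
    }
    rig /= nrg;
  }

  double value = sim + beWeight * be + rigWeight * rig;
  return List::create(_["value"] = value, _["grad"] = grad,
                      _["sim"] = sim, _["be"] = be, _["rig"] = rig);
}
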