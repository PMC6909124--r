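#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cubic uniform B-spline basis on the unit interval and its derivative.
static inline void bspline_weights(double u, double *b) {
  double u2 = u * u, u3 = u2 * u;
  b[0] = (1.0 - 3.0 * u + 3.0 * u2 - u3) / 6.0;
  b[1] = (3.0 * u3 - 6.0 * u2 + 4.0) / 6.0;
  b[2] = (-3.0 * u3 + 3.0 * u2 + 3.0 * u + 1.0) / 6.0;
  b[3] = u3 / 6.0;
}

static inline void bspline_dweights(double u, double *d) {
  double u2 = u * u;
  d[0] = -(1.0 - 2.0 * u + u2) / 2.0;
  d[1] = (9.0 * u2 - 12.0 * u) / 6.0;
  d[2] = (-9.0 * u2 + 6.0 * u + 3.0) / 6.0;
  d[3] = u2 / 2.0;
}

// Locate lattice cell for coordinate t (lattice units); returns base index i
// such that control points i-1 .. i+2 are used, or -1 when out of support.
static inline int lattice_cell(double t, int n, double *u) {
  if (t < 1.0 - 1e-9 || t > (double)(n - 2) + 1e-9) return -1;
  int i = (int)std::floor(t);
  if (i < 1) i = 1;
  if (i > n - 3) i = n - 3;
  *u = t - i;
  if (*u < 0.0) *u = 0.0;
  if (*u > 1.0) *u = 1.0;
  return i;
}

// Trilinear / nearest sampling of a 3-D volume at continuous voxel coords.
// w2v is the 3x4 world-to-voxel affine (0-based indices).
// [[Rcpp::export]]
List cpp_sample_volume(NumericVector vol, IntegerVector dim, NumericMatrix w2v,
                       NumericMatrix pts, int nearest, double background) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  LogicalVector inside(n);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    double v[3];
    for (int a = 0; a < 3; ++a)
      v[a] = w2v(a, 0) * x + w2v(a, 1) * y + w2v(a, 2) * z + w2v(a, 3);
    bool ok = v[0] >= -1e-9 && v[0] <= nx - 1 + 1e-9 &&
              v[1] >= -1e-9 && v[1] <= ny - 1 + 1e-9 &&
              v[2] >= -1e-9 && v[2] <= nz - 1 + 1e-9;
    inside[p] = ok;
    if (!ok) { out[p] = background; continue; }
    if (nearest) {
      int i = (int)std::lround(v[0]), j = (int)std::lround(v[1]),
          k = (int)std::lround(v[2]);
      if (i < 0) i = 0; if (i > nx - 1) i = nx - 1;
      if (j < 0) j = 0; if (j > ny - 1) j = ny - 1;
      if (k < 0) k = 0; if (k > nz - 1) k = nz - 1;
      out[p] = vol[i + (size_t)nx * (j + (size_t)ny * k)];
    } else {
      int i0[3]; double d[3]; int dd[3] = {nx, ny, nz};
      for (int a = 0; a < 3; ++a) {
        double va = v[a];
        if (va < 0) va = 0;
        if (va > dd[a] - 1) va = dd[a] - 1;
        int i = (int)std::floor(va);
        if (i > dd[a] - 2) i = dd[a] - 2;
        if (i < 0) i = 0;
        i0[a] = i; d[a] = va - i;
        if (dd[a] == 1) { i0[a] = 0; d[a] = 0.0; }
      }
      double acc = 0.0;
      for (int c = 0; c < 8; ++c) {
        int ii = i0[0] + (c & 1), jj = i0[1] + ((c >> 1) & 1),
            kk = i0[2] + ((c >> 2) & 1);
        if (ii > nx - 1) ii = nx - 1;
        if (jj > ny - 1) jj = ny - 1;
        if (kk > nz - 1) kk = nz - 1;
        double w = ((c & 1) ? d[0] : 1 - d[0]) *
                   (((c >> 1) & 1) ? d[1] : 1 - d[1]) *
                   (((c >> 2) & 1) ? d[2] : 1 - d[2]);
        acc += w * vol[ii + (size_t)nx * (jj + (size_t)ny * kk)];
      }
      out[p] = acc;
    }
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Evaluate a cubic B-spline free-form displacement (and optionally its
// spatial Jacobian, d u_a / d x_b) at world points. Lattice axes are
// world-axis aligned. coef layout: [i, j, k, axis], column-major.
// [[Rcpp::export]]
List cpp_bspline_eval(NumericVector coef, IntegerVector cdim,
                      NumericVector corig, NumericVector cspac,
                      NumericMatrix pts, int want_jac) {
  int nx = cdim[0], ny = cdim[1], nz = cdim[2];
  size_t ncp = (size_t)nx * ny * nz;
  int n = pts.nrow();
  NumericMatrix disp(n, 3);
  LogicalVector inside(n);
  NumericMatrix jac(want_jac ? n : 1, want_jac ? 9 : 1);
  for (int p = 0; p < n; ++p) {
    double u[3]; int base[3]; bool ok = true;
    for (int a = 0; a < 3; ++a) {
      double t = (pts(p, a) - corig[a]) / cspac[a];
      base[a] = lattice_cell(t, a == 0 ? nx : (a == 1 ? ny : nz), &u[a]);
      if (base[a] < 0) ok = false;
    }
    inside[p] = ok;
    if (!ok) continue;
    double bx[4], by[4], bz[4], dx[4], dy[4], dz[4];
    bspline_weights(u[0], bx); bspline_weights(u[1], by); bspline_weights(u[2], bz);
    if (want_jac) {
      bspline_dweights(u[0], dx); bspline_dweights(u[1], dy); bspline_dweights(u[2], dz);
    }
    double acc[3] = {0, 0, 0}, jacc[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (int kz = 0; kz < 4; ++kz) {
      int gz = base[2] - 1 + kz;
      for (int ky = 0; ky < 4; ++ky) {
        int gy = base[1] - 1 + ky;
        double byz = by[ky] * bz[kz];
        for (int kx = 0; kx < 4; ++kx) {
          int gx = base[0] - 1 + kx;
          size_t idx = (size_t)gx + (size_t)nx * (gy + (size_t)ny * gz);
          double w = bx[kx] * byz;
          for (int a = 0; a < 3; ++a) {
            double c = coef[idx + a * ncp];
            acc[a] += w * c;
            if (want_jac) {
              jacc[a + 0] += c * dx[kx] * by[ky] * bz[kz] / cspac[0];
              jacc[a + 3] += c * bx[kx] * dy[ky] * bz[kz] / cspac[1];
              jacc[a + 6] += c * bx[kx] * by[ky] * dz[kz] / cspac[2];
            }
          }
        }
      }
    }
    for (int a = 0; a < 3; ++a) disp(p, a) = acc[a];
    if (want_jac) for (int q = 0; q < 9; ++q) jac(p, q) = jacc[q];
  }
  return List::create(_["disp"] = disp, _["inside"] = inside, _["jac"] = jac);
}

// Per-point 64 control-point indices (0-based, per-axis lattice) and tensor
// weights, for building the sparse basis matrix used by the structure term.
// [[Rcpp::export]]
List cpp_bspline_basis(IntegerVector cdim, NumericVector corig,
                       NumericVector cspac, NumericMatrix pts) {
  int nx = cdim[0], ny = cdim[1], nz = cdim[2];
  int n = pts.nrow();
  IntegerMatrix idx(n, 64);
  NumericMatrix w(n, 64);
  LogicalVector inside(n);
  for (int p = 0; p < n; ++p) {
    double u[3]; int base[3]; bool ok = true;
    for (int a = 0; a < 3; ++a) {
      double t = (pts(p, a) - corig[a]) / cspac[a];
      base[a] = lattice_cell(t, a == 0 ? nx : (a == 1 ? ny : nz), &u[a]);
      if (base[a] < 0) ok = false;
    }
    inside[p] = ok;
    if (!ok) { for (int c = 0; c < 64; ++c) { idx(p, c) = 0; w(p, c) = 0.0; } continue; }
    double bx[4], by[4], bz[4];
    bspline_weights(u[0], bx); bspline_weights(u[1], by); bspline_weights(u[2], bz);
    int c = 0;
    for (int kz = 0; kz < 4; ++kz)
      for (int ky = 0; ky < 4; ++ky)
        for (int kx = 0; kx < 4; ++kx, ++c) {
          int gx = base[0] - 1 + kx, gy = base[1] - 1 + ky, gz = base[2] - 1 + kz;
          idx(p, c) = gx + nx * (gy + ny * gz);
          w(p, c) = bx[kx] * by[ky] * bz[kz];
        }
  }
  return List::create(_["idx"] = idx, _["w"] = w, _["inside"] = inside);
}

// Normalized mutual information with partial-volume interpolation, and its
// analytic gradient with respect to the B-spline coefficients.
//
// base_pts: rigid-baseline-mapped world coordinates of the ROI voxels of the
// fixed image; fbins: their (0-based) fixed intensity bins; mbins: the
// pre-binned moving volume; cdim[0] == 0 disables the deformation (rigid
// cost evaluation). Returns -NMI and, when requested, d(-NMI)/d coef.
// [[Rcpp::export]]
List cpp_nmi_pv(NumericMatrix base_pts, IntegerVector fbins,
                NumericVector coef, IntegerVector cdim, NumericVector corig,
                NumericVector cspac, IntegerVector mbins, IntegerVector mdim,
                NumericMatrix w2v, int nbins, int want_grad) {
  int n = base_pts.nrow();
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  bool ffd = cdim[0] > 0;
  size_t ncp = ffd ? (size_t)cdim[0] * cdim[1] * cdim[2] : 0;
  std::vector<double> H((size_t)nbins * nbins, 0.0);
  std::vector<double> yy(ffd || want_grad ? (size_t)n * 3 : 3);
  std::vector<char> okv(n, 0);
  int n_in = 0;

  for (int p = 0; p < n; ++p) {
    double y[3] = {base_pts(p, 0), base_pts(p, 1), base_pts(p, 2)};
    if (ffd) {
      double u[3]; int base[3]; bool ok = true;
      for (int a = 0; a < 3; ++a) {
        double t = (y[a] - corig[a]) / cspac[a];
        base[a] = lattice_cell(t, cdim[a], &u[a]);
        if (base[a] < 0) ok = false;
      }
      if (!ok) continue;  // outside FFD domain: drop from histogram
      double bx[4], by[4], bz[4];
      bspline_weights(u[0], bx); bspline_weights(u[1], by); bspline_weights(u[2], bz);
      double acc[3] = {0, 0, 0};
      for (int kz = 0; kz < 4; ++kz)
        for (int ky = 0; ky < 4; ++ky)
          for (int kx = 0; kx < 4; ++kx) {
            size_t idx = (size_t)(base[0] - 1 + kx) +
                         (size_t)cdim[0] * ((base[1] - 1 + ky) +
                         (size_t)cdim[1] * (base[2] - 1 + kz));
            double w = bx[kx] * by[ky] * bz[kz];
            for (int a = 0; a < 3; ++a) acc[a] += w * coef[idx + a * ncp];
          }
      for (int a = 0; a < 3; ++a) y[a] += acc[a];
    }
    double v[3];
    for (int a = 0; a < 3; ++a)
      v[a] = w2v(a, 0) * y[0] + w2v(a, 1) * y[1] + w2v(a, 2) * y[2] + w2v(a, 3);
    if (v[0] < 0 || v[0] > nx - 1 || v[1] < 0 || v[1] > ny - 1 ||
        v[2] < 0 || v[2] > nz - 1) continue;
    int i0[3]; double d[3]; int dd[3] = {nx, ny, nz};
    for (int a = 0; a < 3; ++a) {
      int i = (int)std::floor(v[a]);
      if (i > dd[a] - 2) i = dd[a] - 2;
      if (i < 0) i = 0;
      i0[a] = i; d[a] = v[a] - i;
    }
    int f = fbins[p];
    for (int c = 0; c < 8; ++c) {
      int ii = i0[0] + (c & 1), jj = i0[1] + ((c >> 1) & 1),
          kk = i0[2] + ((c >> 2) & 1);
      double w = ((c & 1) ? d[0] : 1 - d[0]) *
                 (((c >> 1) & 1) ? d[1] : 1 - d[1]) *
                 (((c >> 2) & 1) ? d[2] : 1 - d[2]);
      int m = mbins[ii + (size_t)nx * (jj + (size_t)ny * kk)];
      H[(size_t)f + (size_t)nbins * m] += w;
    }
    okv[p] = 1;
    if (ffd || want_grad) { yy[(size_t)p * 3] = y[0]; yy[(size_t)p * 3 + 1] = y[1]; yy[(size_t)p * 3 + 2] = y[2]; }
    ++n_in;
  }
  if (n_in < 16) {
    return List::create(_["cost"] = NA_REAL, _["nmi"] = NA_REAL,
                        _["n_inside"] = n_in, _["grad"] = R_NilValue);
  }
  // epsilon-regularized probabilities so every log is finite
  const double eps = 1e-10;
  double tot = n_in + eps * nbins * (double)nbins;
  std::vector<double> Pf(nbins, 0.0), Pm(nbins, 0.0);
  double Hj = 0.0;
  for (int f = 0; f < nbins; ++f)
    for (int m = 0; m < nbins; ++m) {
      double pr = (H[(size_t)f + (size_t)nbins * m] + eps) / tot;
      Pf[f] += pr; Pm[m] += pr;
      Hj -= pr * std::log(pr);
    }
  double Hf = 0.0, Hm = 0.0;
  for (int b = 0; b < nbins; ++b) {
    Hf -= Pf[b] * std::log(Pf[b]);
    Hm -= Pm[b] * std::log(Pm[b]);
  }
  double nmi = (Hf + Hm) / Hj;
  double cost = -nmi;
  if (!want_grad || !ffd) {
    return List::create(_["cost"] = cost, _["nmi"] = nmi,
                        _["n_inside"] = n_in, _["grad"] = R_NilValue);
  }
  // dcost/dP[f,m], then chain to coefficients through PV weights and basis
  std::vector<double> lf(nbins), lm(nbins);
  for (int b = 0; b < nbins; ++b) {
    lf[b] = 1.0 + std::log(Pf[b]);
    lm[b] = 1.0 + std::log(Pm[b]);
  }
  std::vector<double> cP((size_t)nbins * nbins);
  for (int f = 0; f < nbins; ++f)
    for (int m = 0; m < nbins; ++m) {
      double pr = (H[(size_t)f + (size_t)nbins * m] + eps) / tot;
      double dHj = -(1.0 + std::log(pr));
      double dnmi = (-(lf[f]) - lm[m]) / Hj - nmi / Hj * dHj;
      cP[(size_t)f + (size_t)nbins * m] = -dnmi / tot;
    }
  NumericVector grad(ncp * 3);
  for (int p = 0; p < n; ++p) {
    if (!okv[p]) continue;
    double y[3] = {yy[(size_t)p * 3], yy[(size_t)p * 3 + 1], yy[(size_t)p * 3 + 2]};
    double v[3];
    for (int a = 0; a < 3; ++a)
      v[a] = w2v(a, 0) * y[0] + w2v(a, 1) * y[1] + w2v(a, 2) * y[2] + w2v(a, 3);
    int i0[3]; double d[3]; int dd[3] = {nx, ny, nz};
    for (int a = 0; a < 3; ++a) {
      int i = (int)std::floor(v[a]);
      if (i > dd[a] - 2) i = dd[a] - 2;
      if (i < 0) i = 0;
      i0[a] = i; d[a] = v[a] - i;
    }
    int f = fbins[p];
    double gv[3] = {0, 0, 0};
    for (int c = 0; c < 8; ++c) {
      int sx = c & 1, sy = (c >> 1) & 1, sz = (c >> 2) & 1;
      int ii = i0[0] + sx, jj = i0[1] + sy, kk = i0[2] + sz;
      int m = mbins[ii + (size_t)nx * (jj + (size_t)ny * kk)];
      double cc = cP[(size_t)f + (size_t)nbins * m];
      double fx = sx ? d[0] : 1 - d[0], gx = sx ? 1.0 : -1.0;
      double fy = sy ? d[1] : 1 - d[1], gy = sy ? 1.0 : -1.0;
      double fz = sz ? d[2] : 1 - d[2], gz = sz ? 1.0 : -1.0;
      gv[0] += cc * gx * fy * fz;
      gv[1] += cc * fx * gy * fz;
      gv[2] += cc * fx * fy * gz;
    }
    // d v / d y = linear part of w2v; then scatter through the basis
    double gy[3];
    for (int b = 0; b < 3; ++b)
      gy[b] = gv[0] * w2v(0, b) + gv[1] * w2v(1, b) + gv[2] * w2v(2, b);
    double u[3]; int base[3];
    bool ok = true;
    for (int a = 0; a < 3; ++a) {
      double t = (base_pts(p, a) - corig[a]) / cspac[a];
      base[a] = lattice_cell(t, cdim[a], &u[a]);
      if (base[a] < 0) ok = false;
    }
    if (!ok) continue;
    double bx[4], by[4], bz[4];
    bspline_weights(u[0], bx); bspline_weights(u[1], by); bspline_weights(u[2], bz);
    for (int kz = 0; kz < 4; ++kz)
      for (int ky = 0; ky < 4; ++ky)
        for (int kx = 0; kx < 4; ++kx) {
          size_t idx = (size_t)(base[0] - 1 + kx) +
                       (size_t)cdim[0] * ((base[1] - 1 + ky) +
                       (size_t)cdim[1] * (base[2] - 1 + kz));
          double w = bx[kx] * by[ky] * bz[kz];
          for (int a = 0; a < 3; ++a) grad[idx + a * ncp] += w * gy[a];
        }
  }
  return List::create(_["cost"] = cost, _["nmi"] = nmi,
                      _["n_inside"] = n_in, _["grad"] = grad);
}

// For each row of `from`, the minimum Euclidean distance to any row of `to`.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix from, NumericMatrix to) {
  int n = from.nrow(), m = to.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double x = from(i, 0), y = from(i, 1), z = from(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = x - to(j, 0), dy = y - to(j, 1), dz = z - to(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Separable Gaussian smoothing (sigma in voxels per axis, reflected edges).
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector vol, IntegerVector dim,
                           NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  int nn[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); sum += k[i + r]; }
    for (auto &v : k) v /= sum;
    int n_ax = nn[ax];
    size_t st = stride[ax];
    // iterate over all lines along axis ax
    size_t o1 = stride[(ax + 1) % 3], o2 = stride[(ax + 2) % 3];
    int n1 = nn[(ax + 1) % 3], n2 = nn[(ax + 2) % 3];
    for (int j2 = 0; j2 < n2; ++j2)
      for (int j1 = 0; j1 < n1; ++j1) {
        size_t base = o1 * j1 + o2 * j2;
        for (int i = 0; i < n_ax; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int ii = i + t;
            if (ii < 0) ii = -ii;                       // reflect
            if (ii > n_ax - 1) ii = 2 * (n_ax - 1) - ii;
            if (ii < 0) ii = 0;
            acc += k[t + r] * a[base + st * ii];
          }
          b[base + st * i] = acc;
        }
      }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
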