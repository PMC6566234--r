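#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Uniform cubic B-spline basis on [0,1), weights for control points
// floor(t)-1 .. floor(t)+2.
static inline void bspline_weights(double f, double* w) {
  const double f2 = f * f, f3 = f2 * f;
  w[0] = (1.0 - 3.0 * f + 3.0 * f2 - f3) / 6.0;
  w[1] = (3.0 * f3 - 6.0 * f2 + 4.0) / 6.0;
  w[2] = (-3.0 * f3 + 3.0 * f2 + 3.0 * f + 1.0) / 6.0;
  w[3] = f3 / 6.0;
}

struct BSplineField {
  const double* coef; // [nx, ny, nz, 3] column-major
  int nx, ny, nz;
  double ox, oy, oz, sx, sy, sz;
  bool active;
};

// Displacement of the free-form deformation at physical point (x, y, z).
static inline void ffd_displacement(const BSplineField& b, double x, double y,
                                    double z, double* u) {
  u[0] = u[1] = u[2] = 0.0;
  if (!b.active) return;
  const double tx = (x - b.ox) / b.sx;
  const double ty = (y - b.oy) / b.sy;
  const double tz = (z - b.oz) / b.sz;
  const int ix = (int)std::floor(tx), iy = (int)std::floor(ty),
            iz = (int)std::floor(tz);
  double wx[4], wy[4], wz[4];
  bspline_weights(tx - ix, wx);
  bspline_weights(ty - iy, wy);
  bspline_weights(tz - iz, wz);
  const int nxy = b.nx * b.ny;
  const int ncp = nxy * b.nz;
  for (int c = 0; c < 4; ++c) {
    const int kz = iz - 1 + c;
    if (kz < 0 || kz >= b.nz) continue;
    for (int bq = 0; bq < 4; ++bq) {
      const int ky = iy - 1 + bq;
      if (ky < 0 || ky >= b.ny) continue;
      const double wyz = wy[bq] * wz[c];
      for (int a = 0; a < 4; ++a) {
        const int kx = ix - 1 + a;
        if (kx < 0 || kx >= b.nx) continue;
        const double w = wx[a] * wyz;
        const int base = kx + b.nx * ky + nxy * kz;
        u[0] += w * b.coef[base];
        u[1] += w * b.coef[base + ncp];
        u[2] += w * b.coef[base + 2 * ncp];
      }
    }
  }
}

static BSplineField make_field(NumericVector coef, IntegerVector coefDims,
                               NumericVector bsOrigin, NumericVector bsSpacing) {
  BSplineField b;
  b.active = coef.size() > 0;
  if (b.active) {
    b.coef = coef.begin();
    b.nx = coefDims[0]; b.ny = coefDims[1]; b.nz = coefDims[2];
    b.ox = bsOrigin[0]; b.oy = bsOrigin[1]; b.oz = bsOrigin[2];
    b.sx = bsSpacing[0]; b.sy = bsSpacing[1]; b.sz = bsSpacing[2];
  } else {
    b.coef = 0; b.nx = b.ny = b.nz = 0;
    b.ox = b.oy = b.oz = 0.0; b.sx = b.sy = b.sz = 1.0;
  }
  return b;
}

// [[Rcpp::export(name = ".ffd_displacement_cpp")]]
NumericMatrix ffd_displacement_points(NumericMatrix pts, NumericVector coef,
                                      IntegerVector coefDims,
                                      NumericVector bsOrigin,
                                      NumericVector bsSpacing) {
  BSplineField b = make_field(coef, coefDims, bsOrigin, bsSpacing);
  NumericMatrix out(pts.nrow(), 3);
  double u[3];
  for (int r = 0; r < pts.nrow(); ++r) {
    ffd_displacement(b, pts(r, 0), pts(r, 1), pts(r, 2), u);
    out(r, 0) = u[0]; out(r, 1) = u[1]; out(r, 2) = u[2];
  }
  return out;
}

// Trilinear interpolation of mov at continuous 0-based index (cx, cy, cz).
// Returns false (invalid) if outside the grid or any contributing corner is
// flagged invalid. If grad != 0 also returns d(value)/d(continuous index).
static inline bool trilinear(const double* mov, const int* mvalid, int nx,
                             int ny, int nz, double cx, double cy, double cz,
                             double* val, double* grad) {
  if (cx < 0.0 || cy < 0.0 || cz < 0.0 || cx > nx - 1.0 || cy > ny - 1.0 ||
      cz > nz - 1.0)
    return false;
  int i = (int)std::floor(cx), j = (int)std::floor(cy), k = (int)std::floor(cz);
  if (i > nx - 2) i = nx - 2;
  if (j > ny - 2) j = ny - 2;
  if (k > nz - 2) k = nz - 2;
  if (nx == 1) i = 0;
  if (ny == 1) j = 0;
  if (nz == 1) k = 0;
  const double fx = cx - i, fy = cy - j, fz = cz - k;
  const int nxy = nx * ny;
  double c[2][2][2];
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        int ii = i + di, jj = j + dj, kk = k + dk;
        if (ii >= nx) ii = nx - 1;
        if (jj >= ny) jj = ny - 1;
        if (kk >= nz) kk = nz - 1;
        const int v = ii + nx * jj + nxy * kk;
        if (mvalid && !mvalid[v]) return false;
        const double x = mov[v];
        if (ISNAN(x)) return false;
        c[di][dj][dk] = x;
      }
  const double gx = 1.0 - fx, gy = 1.0 - fy, gz = 1.0 - fz;
  *val = gz * (gy * (gx * c[0][0][0] + fx * c[1][0][0]) +
               fy * (gx * c[0][1][0] + fx * c[1][1][0])) +
         fz * (gy * (gx * c[0][0][1] + fx * c[1][0][1]) +
               fy * (gx * c[0][1][1] + fx * c[1][1][1]));
  if (grad) {
    grad[0] = gz * (gy * (c[1][0][0] - c[0][0][0]) +
                    fy * (c[1][1][0] - c[0][1][0])) +
              fz * (gy * (c[1][0][1] - c[0][0][1]) +
                    fy * (c[1][1][1] - c[0][1][1]));
    grad[1] = gz * (gx * (c[0][1][0] - c[0][0][0]) +
                    fx * (c[1][1][0] - c[1][0][0])) +
              fz * (gx * (c[0][1][1] - c[0][0][1]) +
                    fx * (c[1][1][1] - c[1][0][1]));
    grad[2] = gy * (gx * (c[0][0][1] - c[0][0][0]) +
                    fx * (c[1][0][1] - c[1][0][0])) +
              fy * (gx * (c[0][1][1] - c[0][1][0]) +
                    fx * (c[1][1][1] - c[1][1][0]));
  }
  return true;
}

static inline bool nearest(const double* mov, const int* mvalid, int nx,
                           int ny, int nz, double cx, double cy, double cz,
                           double* val) {
  const int i = (int)std::lround(cx), j = (int)std::lround(cy),
            k = (int)std::lround(cz);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
  const int v = i + nx * j + nx * ny * k;
  if (mvalid && !mvalid[v]) return false;
  if (ISNAN(mov[v])) return false;
  *val = mov[v];
  return true;
}

// Resample mov onto the output grid through the composite transform
// y = T (x + u(x)) where x is the physical location of an output voxel,
// u the B-spline displacement (empty coef => none) and T an affine given as
// a 3x4 matrix [R | b]. idx2phys (3x4) maps 0-based output index to physical;
// phys2idx (3x4) maps physical to 0-based mov continuous index.
// [[Rcpp::export(name = ".resample_cpp")]]
List resample_cpp(NumericVector mov, Nullable<LogicalVector> movValid,
                  IntegerVector movDims, IntegerVector outDims,
                  NumericMatrix idx2phys, NumericMatrix phys2idx,
                  NumericMatrix affine, NumericVector coef,
                  IntegerVector coefDims, NumericVector bsOrigin,
                  NumericVector bsSpacing, int interp) {
  const int mx = movDims[0], my = movDims[1], mz = movDims[2];
  const int ox = outDims[0], oy = outDims[1], oz = outDims[2];
  BSplineField b = make_field(coef, coefDims, bsOrigin, bsSpacing);
  std::vector<int> mv;
  const int* mvalid = 0;
  if (movValid.isNotNull()) {
    LogicalVector lv(movValid);
    mv.assign(lv.begin(), lv.end());
    mvalid = mv.data();
  }
  const int n = ox * oy * oz;
  NumericVector out(n, NA_REAL);
  LogicalVector valid(n, false);
  double u[3];
  int v = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++v) {
        const double px = idx2phys(0, 0) * i + idx2phys(0, 1) * j +
                          idx2phys(0, 2) * k + idx2phys(0, 3);
        const double py = idx2phys(1, 0) * i + idx2phys(1, 1) * j +
                          idx2phys(1, 2) * k + idx2phys(1, 3);
        const double pz = idx2phys(2, 0) * i + idx2phys(2, 1) * j +
                          idx2phys(2, 2) * k + idx2phys(2, 3);
        ffd_displacement(b, px, py, pz, u);
        const double qx = px + u[0], qy = py + u[1], qz = pz + u[2];
        const double yx = affine(0, 0) * qx + affine(0, 1) * qy +
                          affine(0, 2) * qz + affine(0, 3);
        const double yy = affine(1, 0) * qx + affine(1, 1) * qy +
                          affine(1, 2) * qz + affine(1, 3);
        const double yz = affine(2, 0) * qx + affine(2, 1) * qy +
                          affine(2, 2) * qz + affine(2, 3);
        const double cx = phys2idx(0, 0) * yx + phys2idx(0, 1) * yy +
                          phys2idx(0, 2) * yz + phys2idx(0, 3);
        const double cy = phys2idx(1, 0) * yx + phys2idx(1, 1) * yy +
                          phys2idx(1, 2) * yz + phys2idx(1, 3);
        const double cz = phys2idx(2, 0) * yx + phys2idx(2, 1) * yy +
                          phys2idx(2, 2) * yz + phys2idx(2, 3);
        double val;
        bool ok = (interp == 0)
                      ? nearest(mov.begin(), mvalid, mx, my, mz, cx, cy, cz, &val)
                      : trilinear(mov.begin(), mvalid, mx, my, mz, cx, cy, cz,
                                  &val, 0);
        if (ok) { out[v] = val; valid[v] = true; }
      }
  return List::create(_["values"] = out, _["valid"] = valid);
}

// Mean-squares metric and its analytic gradient with respect to the FFD
// control-point displacements. fixed lives on the output grid; mov is
// sampled through y = T (x + u(x)). Returns E = mean residual^2, the
// gradient dE/dcoef (same layout as coef) and the overlap count.
// [[Rcpp::export(name = ".ssd_ffd_cpp")]]
List ssd_ffd_cpp(NumericVector fixed, Nullable<LogicalVector> fixedValid,
                 NumericVector mov, Nullable<LogicalVector> movValid,
                 IntegerVector movDims, IntegerVector outDims,
                 NumericMatrix idx2phys, NumericMatrix phys2idx,
                 NumericMatrix affine, NumericVector coef,
                 IntegerVector coefDims, NumericVector bsOrigin,
                 NumericVector bsSpacing) {
  const int mx = movDims[0], my = movDims[1], mz = movDims[2];
  const int ox = outDims[0], oy = outDims[1], oz = outDims[2];
  BSplineField b = make_field(coef, coefDims, bsOrigin, bsSpacing);
  std::vector<int> mv;
  const int* mvalid = 0;
  if (movValid.isNotNull()) {
    LogicalVector lv(movValid);
    mv.assign(lv.begin(), lv.end());
    mvalid = mv.data();
  }
  std::vector<int> fv;
  const int* fvalid = 0;
  if (fixedValid.isNotNull()) {
    LogicalVector lv(fixedValid);
    fv.assign(lv.begin(), lv.end());
    fvalid = lv.size() ? fv.data() : 0;
  }
  NumericVector grad(coef.size(), 0.0);
  double sse = 0.0;
  long nused = 0;
  // d(mov continuous index)/d(phys) and T's linear part, for the chain rule
  double P[3][3], Rm[3][3];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) {
      P[r][c] = phys2idx(r, c);
      Rm[r][c] = affine(r, c);
    }
  const int ncp = b.active ? b.nx * b.ny * b.nz : 0;
  double u[3], gci[3];
  int v = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++v) {
        if (fvalid && !fvalid[v]) continue;
        const double F = fixed[v];
        if (ISNAN(F)) continue;
        const double px = idx2phys(0, 0) * i + idx2phys(0, 1) * j +
                          idx2phys(0, 2) * k + idx2phys(0, 3);
        const double py = idx2phys(1, 0) * i + idx2phys(1, 1) * j +
                          idx2phys(1, 2) * k + idx2phys(1, 3);
        const double pz = idx2phys(2, 0) * i + idx2phys(2, 1) * j +
                          idx2phys(2, 2) * k + idx2phys(2, 3);
        ffd_displacement(b, px, py, pz, u);
        const double qx = px + u[0], qy = py + u[1], qz = pz + u[2];
        const double yx = Rm[0][0] * qx + Rm[0][1] * qy + Rm[0][2] * qz + affine(0, 3);
        const double yy = Rm[1][0] * qx + Rm[1][1] * qy + Rm[1][2] * qz + affine(1, 3);
        const double yz = Rm[2][0] * qx + Rm[2][1] * qy + Rm[2][2] * qz + affine(2, 3);
        const double cx = P[0][0] * yx + P[0][1] * yy + P[0][2] * yz + phys2idx(0, 3);
        const double cy = P[1][0] * yx + P[1][1] * yy + P[1][2] * yz + phys2idx(1, 3);
        const double cz = P[2][0] * yx + P[2][1] * yy + P[2][2] * yz + phys2idx(2, 3);
        double M;
        if (!trilinear(mov.begin(), mvalid, mx, my, mz, cx, cy, cz, &M, gci))
          continue;
        const double r = M - F;
        sse += r * r;
        ++nused;
        if (!b.active) continue;
        // dM/dphys(y) then dM/du = (dM/dy) * R
        double gy[3], gu[3];
        for (int rr = 0; rr < 3; ++rr)
          gy[rr] = gci[0] * P[0][rr] + gci[1] * P[1][rr] + gci[2] * P[2][rr];
        for (int rr = 0; rr < 3; ++rr)
          gu[rr] = gy[0] * Rm[0][rr] + gy[1] * Rm[1][rr] + gy[2] * Rm[2][rr];
        // scatter 2 r * gu * basis weights into the control-point gradient
        const double tx = (px - b.ox) / b.sx;
        const double ty = (py - b.oy) / b.sy;
        const double tz = (pz - b.oz) / b.sz;
        const int ixc = (int)std::floor(tx), iyc = (int)std::floor(ty),
                  izc = (int)std::floor(tz);
        double wx[4], wy[4], wz[4];
        bspline_weights(tx - ixc, wx);
        bspline_weights(ty - iyc, wy);
        bspline_weights(tz - izc, wz);
        const int nxy = b.nx * b.ny;
        for (int c3 = 0; c3 < 4; ++c3) {
          const int kz = izc - 1 + c3;
          if (kz < 0 || kz >= b.nz) continue;
          for (int c2 = 0; c2 < 4; ++c2) {
            const int ky = iyc - 1 + c2;
            if (ky < 0 || ky >= b.ny) continue;
            const double wyz = wy[c2] * wz[c3];
            for (int c1 = 0; c1 < 4; ++c1) {
              const int kx = ixc - 1 + c1;
              if (kx < 0 || kx >= b.nx) continue;
              const double w = 2.0 * r * wx[c1] * wyz;
              const int base = kx + b.nx * ky + nxy * kz;
              grad[base] += w * gu[0];
              grad[base + ncp] += w * gu[1];
              grad[base + 2 * ncp] += w * gu[2];
            }
          }
        }
      }
  if (nused > 0) {
    sse /= (double)nused;
    for (int g = 0; g < grad.size(); ++g) grad[g] /= (double)nused;
  } else {
    sse = R_PosInf;
  }
  return List::create(_["value"] = sse, _["gradient"] = grad,
                      _["n"] = (double)nused);
}

// Separable Gaussian smoothing with reflected boundaries; sigma in voxels
// per axis, kernel truncated at 3 sigma. sigma <= 0 leaves an axis untouched.
// [[Rcpp::export(name = ".gaussian_smooth_cpp")]]
NumericVector gaussian_smooth_cpp(NumericVector values, IntegerVector dims,
                                  NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> cur(values.begin(), values.end());
  std::vector<double> nxt(cur.size());
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0.0) continue;
    const int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * rad + 1);
    double ksum = 0.0;
    for (int t = -rad; t <= rad; ++t) {
      kern[t + rad] = std::exp(-0.5 * t * t / (s * s));
      ksum += kern[t + rad];
    }
    for (size_t t = 0; t < kern.size(); ++t) kern[t] /= ksum;
    const int len = n[ax], st = stride[ax];
    const int nlines = (int)cur.size() / len;
    // iterate over all lines along axis ax
    int done = 0;
    for (int k = 0; k < (ax == 2 ? 1 : nz); ++k)
      for (int j = 0; j < (ax == 1 ? 1 : ny); ++j)
        for (int i = 0; i < (ax == 0 ? 1 : nx); ++i) {
          const int base = i + nx * j + nx * ny * k;
          for (int t = 0; t < len; ++t) {
            double acc = 0.0;
            for (int d = -rad; d <= rad; ++d) {
              int p = t + d;
              if (p < 0) p = -p - 1;            // reflect
              if (p >= len) p = 2 * len - 1 - p;
              if (p < 0) p = 0;
              acc += kern[d + rad] * cur[base + p * st];
            }
            nxt[base + t * st] = acc;
          }
          ++done;
        }
    (void)nlines; (void)done;
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}
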