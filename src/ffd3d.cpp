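#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Cubic B-spline free-form deformation engine.
//
// A control-point lattice with integer voxel spacing delta = (dx,dy,dz)
// covers the reference voxel grid. Voxel v lies in lattice cell i = v / d
// with local coordinate t = (v mod d) / d, and its displacement interpolates
// the 4x4x4 surrounding control points through the cubic B-spline basis.
// Control point array position a (0-based) corresponds to lattice index
// a - 1, so cell i uses array positions i .. i+3 per axis, and the array has
// (n-1)/d + 4 control points per axis.
//
// Units: coefficients, displacements and spatial derivatives are all in
// voxel units of the lattice's domain grid; callers convert mm <-> voxels.

static inline void bspline_w(double t, double *w) {
  double it = 1.0 - t;
  w[0] = it * it * it / 6.0;
  w[1] = (3 * t * t * t - 6 * t * t + 4) / 6.0;
  w[2] = (-3 * t * t * t + 3 * t * t + 3 * t + 1) / 6.0;
  w[3] = t * t * t / 6.0;
}
static inline void bspline_dw(double t, double *w) {
  double it = 1.0 - t;
  w[0] = -it * it / 2.0;
  w[1] = (3 * t * t - 4 * t) / 2.0;
  w[2] = (-3 * t * t + 2 * t + 1) / 2.0;
  w[3] = t * t / 2.0;
}
static inline void bspline_d2w(double t, double *w) {
  w[0] = 1.0 - t;
  w[1] = 3 * t - 2;
  w[2] = 1 - 3 * t;
  w[3] = t;
}

struct BasisTables {
  // per axis: delta residues x 4 taps, value/1st/2nd derivative
  std::vector<double> w[3], dw[3], d2w[3];
  int d[3];
  void init(const int *delta) {
    for (int ax = 0; ax < 3; ax++) {
      d[ax] = delta[ax];
      w[ax].resize(delta[ax] * 4);
      dw[ax].resize(delta[ax] * 4);
      d2w[ax].resize(delta[ax] * 4);
      for (int r = 0; r < delta[ax]; r++) {
        double t = (double)r / delta[ax];
        double b[4];
        bspline_w(t, b);
        for (int l = 0; l < 4; l++) w[ax][r * 4 + l] = b[l];
        bspline_dw(t, b);
        for (int l = 0; l < 4; l++) dw[ax][r * 4 + l] = b[l] / delta[ax];
        bspline_d2w(t, b);
        for (int l = 0; l < 4; l++)
          d2w[ax][r * 4 + l] = b[l] / ((double)delta[ax] * delta[ax]);
      }
    }
  }
};

static inline int binof(double v, int nbins) {
  int b = (int)(v * nbins / 256.0);
  if (b < 0) b = 0;
  if (b >= nbins) b = nbins - 1;
  return b;
}

static inline double xlogx(double c) { return c > 0 ? c * std::log(c) : 0.0; }

static inline double det3(const double *J) {
  return J[0] * (J[4] * J[8] - J[5] * J[7]) -
         J[1] * (J[3] * J[8] - J[5] * J[6]) +
         J[2] * (J[3] * J[7] - J[4] * J[6]);
}

// Displacement field (coef units) at every voxel of the domain grid.
// [[Rcpp::export]]
NumericVector ffd_field_cpp(NumericVector coef, IntegerVector cdim,
                            IntegerVector delta, IntegerVector shape) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  size_t ncp = (size_t)ncx * ncy * ncz;
  int dl[3] = {delta[0], delta[1], delta[2]};
  BasisTables tb;
  tb.init(dl);
  size_t N = (size_t)nx * ny * nz;
  NumericVector out(N * 3);
  const double *cf = coef.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; z++) {
    int iz = z / dl[2], rz = z % dl[2];
    for (int y = 0; y < ny; y++) {
      int iy = y / dl[1], ry = y % dl[1];
      for (int x = 0; x < nx; x++) {
        int ix = x / dl[0], rx = x % dl[0];
        double u0 = 0, u1 = 0, u2 = 0;
        for (int n = 0; n < 4; n++) {
          double wz = tb.w[2][rz * 4 + n];
          size_t az = (size_t)(iz + n) * ncx * ncy;
          for (int m = 0; m < 4; m++) {
            double wyz = tb.w[1][ry * 4 + m] * wz;
            size_t ayz = az + (size_t)(iy + m) * ncx;
            const double *c0 = cf + ayz + ix;
            for (int l = 0; l < 4; l++) {
              double w = tb.w[0][rx * 4 + l] * wyz;
              u0 += w * c0[l];
              u1 += w * c0[l + ncp];
              u2 += w * c0[l + 2 * ncp];
            }
          }
        }
        size_t vi = x + (size_t)y * nx + (size_t)z * nx * ny;
        o[vi] = u0;
        o[vi + N] = u1;
        o[vi + 2 * N] = u2;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// Displacement at arbitrary (fractional, possibly out-of-domain) voxel
// coordinates; cells are clamped so the spline extrapolates smoothly.
// [[Rcpp::export]]
NumericMatrix ffd_disp_points_cpp(NumericVector coef, IntegerVector cdim,
                                  IntegerVector delta, NumericMatrix pts) {
  int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  size_t ncp = (size_t)ncx * ncy * ncz;
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  const double *cf = coef.begin();
  int nc[3] = {ncx, ncy, ncz};
  for (int p = 0; p < n; p++) {
    double t[3];
    int ic[3];
    for (int ax = 0; ax < 3; ax++) {
      double u = pts(p, ax) / delta[ax];
      int i = (int)std::floor(u);
      int imax = nc[ax] - 4;
      if (i < 0) i = 0;
      if (i > imax) i = imax;
      ic[ax] = i;
      t[ax] = u - i;
    }
    double wx[4], wy[4], wz[4];
    bspline_w(t[0], wx);
    bspline_w(t[1], wy);
    bspline_w(t[2], wz);
    double u0 = 0, u1 = 0, u2 = 0;
    for (int nn = 0; nn < 4; nn++)
      for (int m = 0; m < 4; m++) {
        double wyz = wy[m] * wz[nn];
        size_t ayz = (size_t)(ic[2] + nn) * ncx * ncy + (size_t)(ic[1] + m) * ncx + ic[0];
        for (int l = 0; l < 4; l++) {
          double w = wx[l] * wyz;
          u0 += w * cf[ayz + l];
          u1 += w * cf[ayz + l + ncp];
          u2 += w * cf[ayz + l + 2 * ncp];
        }
      }
    out(p, 0) = u0;
    out(p, 1) = u1;
    out(p, 2) = u2;
  }
  return out;
}

// Regularizer terms over every voxel of the domain: bending energy sum,
// |log|det J|| sum, Jacobian statistics, optional determinant map.
// [[Rcpp::export]]
List ffd_terms_cpp(NumericVector coef, IntegerVector cdim, IntegerVector delta,
                   IntegerVector shape, bool want_detmap) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  size_t ncp = (size_t)ncx * ncy * ncz;
  int dl[3] = {delta[0], delta[1], delta[2]};
  BasisTables tb;
  tb.init(dl);
  size_t N = (size_t)nx * ny * nz;
  const double *cf = coef.begin();
  NumericVector detmap(want_detmap ? N : 0);
  double be = 0, jl = 0, mindet = R_PosInf;
  int nfold = 0;
  for (int z = 0; z < nz; z++) {
    int iz = z / dl[2], rz = z % dl[2];
    for (int y = 0; y < ny; y++) {
      int iy = y / dl[1], ry = y % dl[1];
      for (int x = 0; x < nx; x++) {
        int ix = x / dl[0], rx = x % dl[0];
        double d1[9] = {0}, d2[18] = {0};
        for (int n = 0; n < 4; n++) {
          double wz = tb.w[2][rz * 4 + n], dz = tb.dw[2][rz * 4 + n],
                 ddz = tb.d2w[2][rz * 4 + n];
          size_t az = (size_t)(iz + n) * ncx * ncy;
          for (int m = 0; m < 4; m++) {
            double wy = tb.w[1][ry * 4 + m], dy = tb.dw[1][ry * 4 + m],
                   ddy = tb.d2w[1][ry * 4 + m];
            size_t ayz = az + (size_t)(iy + m) * ncx + ix;
            for (int l = 0; l < 4; l++) {
              double wx = tb.w[0][rx * 4 + l], dx = tb.dw[0][rx * 4 + l],
                     ddx = tb.d2w[0][rx * 4 + l];
              double gx = dx * wy * wz, gy = wx * dy * wz, gz = wx * wy * dz;
              double hxx = ddx * wy * wz, hyy = wx * ddy * wz, hzz = wx * wy * ddz;
              double hxy = dx * dy * wz, hxz = dx * wy * dz, hyz = wx * dy * dz;
              for (int k = 0; k < 3; k++) {
                double c = cf[ayz + l + (size_t)k * ncp];
                d1[k * 3 + 0] += gx * c;
                d1[k * 3 + 1] += gy * c;
                d1[k * 3 + 2] += gz * c;
                d2[k * 6 + 0] += hxx * c;
                d2[k * 6 + 1] += hyy * c;
                d2[k * 6 + 2] += hzz * c;
                d2[k * 6 + 3] += hxy * c;
                d2[k * 6 + 4] += hxz * c;
                d2[k * 6 + 5] += hyz * c;
              }
            }
          }
        }
        for (int k = 0; k < 3; k++) {
          be += d2[k * 6] * d2[k * 6] + d2[k * 6 + 1] * d2[k * 6 + 1] +
                d2[k * 6 + 2] * d2[k * 6 + 2] +
                2 * (d2[k * 6 + 3] * d2[k * 6 + 3] +
                     d2[k * 6 + 4] * d2[k * 6 + 4] +
                     d2[k * 6 + 5] * d2[k * 6 + 5]);
        }
        double J[9];
        for (int k = 0; k < 3; k++)
          for (int j = 0; j < 3; j++) J[k * 3 + j] = (k == j) + d1[k * 3 + j];
        double dt = det3(J);
        if (dt < mindet) mindet = dt;
        if (dt <= 1e-6) nfold++;
        jl += std::fabs(std::log(std::max(std::fabs(dt), 1e-12)));
        if (want_detmap)
          detmap[x + (size_t)y * nx + (size_t)z * nx * ny] = dt;
      }
    }
  }
  List out = List::create(_["be_sum"] = be, _["jl_sum"] = jl,
                          _["n"] = (double)N, _["min_det"] = mindet,
                          _["n_fold"] = nfold);
  if (want_detmap) {
    detmap.attr("dim") = IntegerVector::create(nx, ny, nz);
    out["detmap"] = detmap;
  }
  return out;
}

struct CostState {
  std::vector<double> u, d1, d2, det;
  std::vector<int> b2; // -2 not eligible for NMI, -1 out of moving domain
  std::vector<int> b1;
  std::vector<double> joint, m1, m2;
  double S1, S2, S12, Nv, be_sum, jl_sum;
  double mindet;
  int nfold;
};

static void compute_state(const double *ref, const double *movA, int nx, int ny,
                          int nz, const double *cf, int ncx, int ncy, int ncz,
                          const int *dl, int nbins, const int *mask,
                          CostState &st, bool keep_cache) {
  size_t N = (size_t)nx * ny * nz;
  size_t ncp = (size_t)ncx * ncy * ncz;
  BasisTables tb;
  tb.init(dl);
  if (keep_cache) {
    st.u.assign(N * 3, 0.0);
    st.d1.assign(N * 9, 0.0);
    st.d2.assign(N * 18, 0.0);
    st.det.assign(N, 1.0);
    st.b2.assign(N, -2);
    st.b1.assign(N, 0);
  }
  st.joint.assign((size_t)nbins * nbins, 0.0);
  st.m1.assign(nbins, 0.0);
  st.m2.assign(nbins, 0.0);
  st.be_sum = st.jl_sum = 0.0;
  st.Nv = 0.0;
  st.mindet = R_PosInf;
  st.nfold = 0;
  for (int z = 0; z < nz; z++) {
    int iz = z / dl[2], rz = z % dl[2];
    for (int y = 0; y < ny; y++) {
      int iy = y / dl[1], ry = y % dl[1];
      for (int x = 0; x < nx; x++) {
        int ix = x / dl[0], rx = x % dl[0];
        double u[3] = {0}, d1[9] = {0}, d2[18] = {0};
        for (int n = 0; n < 4; n++) {
          double wz = tb.w[2][rz * 4 + n], dz = tb.dw[2][rz * 4 + n],
                 ddz = tb.d2w[2][rz * 4 + n];
          size_t az = (size_t)(iz + n) * ncx * ncy;
          for (int m = 0; m < 4; m++) {
            double wy = tb.w[1][ry * 4 + m], dy = tb.dw[1][ry * 4 + m],
                   ddy = tb.d2w[1][ry * 4 + m];
            size_t ayz = az + (size_t)(iy + m) * ncx + ix;
            for (int l = 0; l < 4; l++) {
              double wx = tb.w[0][rx * 4 + l], dx = tb.dw[0][rx * 4 + l],
                     ddx = tb.d2w[0][rx * 4 + l];
              double w0 = wx * wy * wz;
              double gx = dx * wy * wz, gy = wx * dy * wz, gz = wx * wy * dz;
              double hxx = ddx * wy * wz, hyy = wx * ddy * wz, hzz = wx * wy * ddz;
              double hxy = dx * dy * wz, hxz = dx * wy * dz, hyz = wx * dy * dz;
              for (int k = 0; k < 3; k++) {
                double c = cf[ayz + l + (size_t)k * ncp];
                u[k] += w0 * c;
                d1[k * 3 + 0] += gx * c;
                d1[k * 3 + 1] += gy * c;
                d1[k * 3 + 2] += gz * c;
                d2[k * 6 + 0] += hxx * c;
                d2[k * 6 + 1] += hyy * c;
                d2[k * 6 + 2] += hzz * c;
                d2[k * 6 + 3] += hxy * c;
                d2[k * 6 + 4] += hxz * c;
                d2[k * 6 + 5] += hyz * c;
              }
            }
          }
        }
        size_t vi = x + (size_t)y * nx + (size_t)z * nx * ny;
        for (int k = 0; k < 3; k++)
          st.be_sum += d2[k * 6] * d2[k * 6] + d2[k * 6 + 1] * d2[k * 6 + 1] +
                       d2[k * 6 + 2] * d2[k * 6 + 2] +
                       2 * (d2[k * 6 + 3] * d2[k * 6 + 3] +
                            d2[k * 6 + 4] * d2[k * 6 + 4] +
                            d2[k * 6 + 5] * d2[k * 6 + 5]);
        double J[9];
        for (int k = 0; k < 3; k++)
          for (int j = 0; j < 3; j++) J[k * 3 + j] = (k == j) + d1[k * 3 + j];
        double dt = det3(J);
        if (dt < st.mindet) st.mindet = dt;
        if (dt <= 1e-6) st.nfold++;
        st.jl_sum += std::fabs(std::log(std::max(std::fabs(dt), 1e-12)));
        int b1 = binof(ref[vi], nbins);
        int b2 = -2;
        if (!mask || mask[vi]) {
          bool ok;
          extern double tri_sample_proxy(const double *, int, int, int, double,
                                         double, double, bool &);
          double v = tri_sample_proxy(movA, nx, ny, nz, x + u[0], y + u[1],
                                      z + u[2], ok);
          if (ok) {
            b2 = binof(v, nbins);
            st.joint[(size_t)b1 * nbins + b2] += 1;
            st.m1[b1] += 1;
            st.m2[b2] += 1;
            st.Nv += 1;
          } else {
            b2 = -1;
          }
        }
        if (keep_cache) {
          for (int k = 0; k < 3; k++) st.u[vi + k * N] = u[k];
          for (int k = 0; k < 9; k++) st.d1[vi * 9 + k] = d1[k];
          for (int k = 0; k < 18; k++) st.d2[vi * 18 + k] = d2[k];
          st.det[vi] = dt;
          st.b1[vi] = b1;
          st.b2[vi] = b2;
        }
      }
    }
  }
  st.S1 = st.S2 = st.S12 = 0.0;
  for (int b = 0; b < nbins; b++) {
    st.S1 += xlogx(st.m1[b]);
    st.S2 += xlogx(st.m2[b]);
  }
  for (size_t b = 0; b < (size_t)nbins * nbins; b++) st.S12 += xlogx(st.joint[b]);
}

// local duplicate of the trilinear sampler (kept in interp.cpp for export)
double tri_sample_proxy(const double *d, int nx, int ny, int nz, double x,
                        double y, double z, bool &ok) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    ok = false;
    return 0.0;
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  const double *p = d + x0 * sx + (size_t)y0 * sy + (size_t)z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double v = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
             (c01 * (1 - fy) + c11 * fy) * fz;
  if (ISNAN(v)) { ok = false; return 0.0; }
  ok = true;
  return v;
}

static double nmi_from(double S1, double S2, double S12, double Nv) {
  if (Nv <= 0) return 1.0;
  double H1 = std::log(Nv) - S1 / Nv;
  double H2 = std::log(Nv) - S2 / Nv;
  double H12 = std::log(Nv) - S12 / Nv;
  if (H12 <= 0) return 2.0;
  return (H1 + H2) / H12;
}

static List cost_breakdown(const CostState &st, size_t N, double w1, double w2) {
  double nmi = nmi_from(st.S1, st.S2, st.S12, st.Nv);
  double be = st.be_sum / N, jl = st.jl_sum / N;
  double total = -(1 - w1 - w2) * nmi + w1 * be + w2 * jl;
  return List::create(_["total"] = total, _["nmi"] = nmi, _["be"] = be,
                      _["jl"] = jl, _["be_sum"] = st.be_sum,
                      _["jl_sum"] = st.jl_sum, _["n_valid"] = st.Nv,
                      _["min_det"] = st.mindet, _["n_fold"] = st.nfold);
}

// [[Rcpp::export]]
List ffd_cost_cpp(NumericVector ref, NumericVector movA, IntegerVector shape,
                  NumericVector coef, IntegerVector cdim, IntegerVector delta,
                  int nbins, double w1, double w2, IntegerVector mask) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  int dl[3] = {delta[0], delta[1], delta[2]};
  CostState st;
  compute_state(ref.begin(), movA.begin(), nx, ny, nz, coef.begin(), cdim[0],
                cdim[1], cdim[2], dl, nbins, mask.size() ? mask.begin() : NULL,
                st, false);
  return cost_breakdown(st, (size_t)nx * ny * nz, w1, w2);
}

// Central finite-difference gradient of the total cost with respect to every
// control-point displacement component. Perturbing one control point only
// touches voxels in its 4-cell support, so the joint histogram, bending and
// Jacobian sums are updated locally instead of recomputed.
// [[Rcpp::export]]
List ffd_grad_cpp(NumericVector ref, NumericVector movA, IntegerVector shape,
                  NumericVector coef, IntegerVector cdim, IntegerVector delta,
                  int nbins, double w1, double w2, IntegerVector mask,
                  double eps) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  int dl[3] = {delta[0], delta[1], delta[2]};
  size_t N = (size_t)nx * ny * nz;
  size_t ncp = (size_t)ncx * ncy * ncz;
  const int *mk = mask.size() ? mask.begin() : NULL;
  CostState st;
  compute_state(ref.begin(), movA.begin(), nx, ny, nz, coef.begin(), ncx, ncy,
                ncz, dl, nbins, mk, st, true);
  BasisTables tb;
  tb.init(dl);
  NumericVector grad(ncp * 3);
  const double *movp = movA.begin();
  double A = 1 - w1 - w2;
  std::vector<double> dm1p(nbins), dm2p(nbins), dm1m(nbins), dm2m(nbins);
  for (int az = 0; az < ncz; az++) {
    int zlo = std::max(0, (az - 3) * dl[2]);
    int zhi = std::min(nz - 1, (az + 1) * dl[2] - 1);
    if (zlo > zhi) continue;
    for (int ay = 0; ay < ncy; ay++) {
      int ylo = std::max(0, (ay - 3) * dl[1]);
      int yhi = std::min(ny - 1, (ay + 1) * dl[1] - 1);
      if (ylo > yhi) continue;
      for (int ax = 0; ax < ncx; ax++) {
        int xlo = std::max(0, (ax - 3) * dl[0]);
        int xhi = std::min(nx - 1, (ax + 1) * dl[0] - 1);
        if (xlo > xhi) continue;
        for (int k = 0; k < 3; k++) {
          double dbe_p = 0, dbe_m = 0, djl_p = 0, djl_m = 0;
          std::unordered_map<int, double> djp, djm;
          std::vector<int> t1, t2;
          std::fill(dm1p.begin(), dm1p.end(), 0.0);
          std::fill(dm2p.begin(), dm2p.end(), 0.0);
          std::fill(dm1m.begin(), dm1m.end(), 0.0);
          std::fill(dm2m.begin(), dm2m.end(), 0.0);
          double dNp = 0, dNm = 0;
          for (int z = zlo; z <= zhi; z++) {
            int iz = z / dl[2], lz = az - iz;
            if (lz < 0 || lz > 3) continue;
            int rz = z % dl[2];
            double wz = tb.w[2][rz * 4 + lz], dz = tb.dw[2][rz * 4 + lz],
                   ddz = tb.d2w[2][rz * 4 + lz];
            for (int y = ylo; y <= yhi; y++) {
              int iy = y / dl[1], ly = ay - iy;
              if (ly < 0 || ly > 3) continue;
              int ry = y % dl[1];
              double wy = tb.w[1][ry * 4 + ly], dy = tb.dw[1][ry * 4 + ly],
                     ddy = tb.d2w[1][ry * 4 + ly];
              for (int x = xlo; x <= xhi; x++) {
                int ixc = x / dl[0], lx = ax - ixc;
                if (lx < 0 || lx > 3) continue;
                int rx = x % dl[0];
                double wx = tb.w[0][rx * 4 + lx], dx = tb.dw[0][rx * 4 + lx],
                       ddx = tb.d2w[0][rx * 4 + lx];
                double w0 = wx * wy * wz;
                double gx = dx * wy * wz, gy = wx * dy * wz, gz = wx * wy * dz;
                double h[6] = {ddx * wy * wz, wx * ddy * wz, wx * wy * ddz,
                               dx * dy * wz, dx * wy * dz, wx * dy * dz};
                size_t vi = x + (size_t)y * nx + (size_t)z * nx * ny;
                // bending energy delta (component k only)
                const double *d2v = &st.d2[vi * 18 + k * 6];
                static const double cc[6] = {1, 1, 1, 2, 2, 2};
                for (int tI = 0; tI < 6; tI++) {
                  double base = 2 * d2v[tI] * h[tI] * eps;
                  double quad = cc[tI] * h[tI] * h[tI] * eps * eps;
                  dbe_p += cc[tI] * base + quad;
                  dbe_m += -cc[tI] * base + quad;
                }
                // jacobian delta: row k of J shifts by +-eps*(gx,gy,gz)
                const double *d1v = &st.d1[vi * 9];
                double J[9];
                for (int kk = 0; kk < 3; kk++)
                  for (int j = 0; j < 3; j++)
                    J[kk * 3 + j] = (kk == j) + d1v[kk * 3 + j];
                double oldterm =
                    std::fabs(std::log(std::max(std::fabs(st.det[vi]), 1e-12)));
                double Jp[9], Jm[9];
                std::copy(J, J + 9, Jp);
                std::copy(J, J + 9, Jm);
                Jp[k * 3 + 0] += eps * gx;
                Jp[k * 3 + 1] += eps * gy;
                Jp[k * 3 + 2] += eps * gz;
                Jm[k * 3 + 0] -= eps * gx;
                Jm[k * 3 + 1] -= eps * gy;
                Jm[k * 3 + 2] -= eps * gz;
                djl_p += std::fabs(std::log(std::max(std::fabs(det3(Jp)), 1e-12))) - oldterm;
                djl_m += std::fabs(std::log(std::max(std::fabs(det3(Jm)), 1e-12))) - oldterm;
                // NMI delta
                int b2old = st.b2[vi];
                if (b2old == -2) continue;
                int b1 = st.b1[vi];
                double px = x + st.u[vi], py = y + st.u[vi + N],
                       pz = z + st.u[vi + 2 * N];
                double qp[3] = {px, py, pz}, qm[3] = {px, py, pz};
                qp[k] += eps * w0;
                qm[k] -= eps * w0;
                bool okp, okm;
                double vp = tri_sample_proxy(movp, nx, ny, nz, qp[0], qp[1], qp[2], okp);
                double vm = tri_sample_proxy(movp, nx, ny, nz, qm[0], qm[1], qm[2], okm);
                int b2p = okp ? binof(vp, nbins) : -1;
                int b2m = okm ? binof(vm, nbins) : -1;
                if (b2p != b2old) {
                  if (b2old >= 0) {
                    djp[b1 * nbins + b2old] -= 1;
                    dm1p[b1] -= 1; dm2p[b2old] -= 1; dNp -= 1;
                    t1.push_back(b1); t2.push_back(b2old);
                  }
                  if (b2p >= 0) {
                    djp[b1 * nbins + b2p] += 1;
                    dm1p[b1] += 1; dm2p[b2p] += 1; dNp += 1;
                    t1.push_back(b1); t2.push_back(b2p);
                  }
                }
                if (b2m != b2old) {
                  if (b2old >= 0) {
                    djm[b1 * nbins + b2old] -= 1;
                    dm1m[b1] -= 1; dm2m[b2old] -= 1; dNm -= 1;
                    t1.push_back(b1); t2.push_back(b2old);
                  }
                  if (b2m >= 0) {
                    djm[b1 * nbins + b2m] += 1;
                    dm1m[b1] += 1; dm2m[b2m] += 1; dNm += 1;
                    t1.push_back(b1); t2.push_back(b2m);
                  }
                }
              }
            }
          }
          // assemble NMI for both signs from the deltas
          double nmi0 = nmi_from(st.S1, st.S2, st.S12, st.Nv);
          double nmip = nmi0, nmim = nmi0;
          if (!djp.empty() || !djm.empty()) {
            double S1p = st.S1, S2p = st.S2, S12p = st.S12;
            double S1m = st.S1, S2m = st.S2, S12m = st.S12;
            for (std::unordered_map<int, double>::iterator it = djp.begin();
                 it != djp.end(); ++it) {
              double c = st.joint[it->first];
              S12p += xlogx(c + it->second) - xlogx(c);
            }
            for (std::unordered_map<int, double>::iterator it = djm.begin();
                 it != djm.end(); ++it) {
              double c = st.joint[it->first];
              S12m += xlogx(c + it->second) - xlogx(c);
            }
            for (size_t ti = 0; ti < t1.size(); ti++) {
              int b = t1[ti];
              if (dm1p[b] != 0) { S1p += xlogx(st.m1[b] + dm1p[b]) - xlogx(st.m1[b]); dm1p[b] = 0; }
              if (dm1m[b] != 0) { S1m += xlogx(st.m1[b] + dm1m[b]) - xlogx(st.m1[b]); dm1m[b] = 0; }
              b = t2[ti];
              if (dm2p[b] != 0) { S2p += xlogx(st.m2[b] + dm2p[b]) - xlogx(st.m2[b]); dm2p[b] = 0; }
              if (dm2m[b] != 0) { S2m += xlogx(st.m2[b] + dm2m[b]) - xlogx(st.m2[b]); dm2m[b] = 0; }
            }
            nmip = nmi_from(S1p, S2p, S12p, st.Nv + dNp);
            nmim = nmi_from(S1m, S2m, S12m, st.Nv + dNm);
          }
          double Cp = -A * nmip + w1 * (st.be_sum + dbe_p) / N +
                      w2 * (st.jl_sum + djl_p) / N;
          double Cm = -A * nmim + w1 * (st.be_sum + dbe_m) / N +
                      w2 * (st.jl_sum + djl_m) / N;
          grad[(size_t)ax + (size_t)ay * ncx + (size_t)az * ncx * ncy + k * ncp] =
              (Cp - Cm) / (2 * eps);
        }
      }
    }
  }
  grad.attr("dim") = IntegerVector::create(ncx, ncy, ncz, 3);
  List cost = cost_breakdown(st, N, w1, w2);
  return List::create(_["grad"] = grad, _["cost"] = cost);
}

// One-step pull-back resampling: out voxel -> (optional FFD in the reference
// domain) -> (optional affine) -> trilinear sample of the moving volume.
// Affine maps physical reference mm to physical moving mm. coef in mm.
// [[Rcpp::export]]
NumericVector warp_resample_cpp(NumericVector mov, IntegerVector mshape,
                                NumericVector mspacing, NumericVector morigin,
                                IntegerVector oshape, NumericVector ospacing,
                                NumericVector oorigin, NumericMatrix Amat,
                                NumericVector Atrans, bool has_ffd,
                                NumericVector coef, IntegerVector cdim,
                                IntegerVector delta, NumericVector fspacing,
                                NumericVector forigin, double fill) {
  int nx = oshape[0], ny = oshape[1], nz = oshape[2];
  int mx = mshape[0], my = mshape[1], mz = mshape[2];
  NumericVector out((size_t)nx * ny * nz);
  const double *mv = mov.begin();
  int nc[3] = {0, 0, 0};
  size_t ncp = 0;
  if (has_ffd) {
    nc[0] = cdim[0]; nc[1] = cdim[1]; nc[2] = cdim[2];
    ncp = (size_t)nc[0] * nc[1] * nc[2];
  }
  const double *cf = has_ffd ? coef.begin() : NULL;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        double p[3] = {oorigin[0] + x * ospacing[0],
                       oorigin[1] + y * ospacing[1],
                       oorigin[2] + z * ospacing[2]};
        if (has_ffd) {
          double t[3];
          int ic[3];
          for (int ax = 0; ax < 3; ax++) {
            double u = (p[ax] - forigin[ax]) / fspacing[ax] / delta[ax];
            int i = (int)std::floor(u);
            int imax = nc[ax] - 4;
            if (i < 0) i = 0;
            if (i > imax) i = imax;
            ic[ax] = i;
            t[ax] = u - i;
          }
          double wx[4], wy[4], wz[4];
          bspline_w(t[0], wx);
          bspline_w(t[1], wy);
          bspline_w(t[2], wz);
          double u0 = 0, u1 = 0, u2 = 0;
          for (int nn = 0; nn < 4; nn++)
            for (int m = 0; m < 4; m++) {
              double wyz = wy[m] * wz[nn];
              size_t ayz = (size_t)(ic[2] + nn) * nc[0] * nc[1] +
                           (size_t)(ic[1] + m) * nc[0] + ic[0];
              for (int l = 0; l < 4; l++) {
                double w = wx[l] * wyz;
                u0 += w * cf[ayz + l];
                u1 += w * cf[ayz + l + ncp];
                u2 += w * cf[ayz + l + 2 * ncp];
              }
            }
          p[0] += u0; p[1] += u1; p[2] += u2;
        }
        double q[3];
        for (int r = 0; r < 3; r++)
          q[r] = Amat(r, 0) * p[0] + Amat(r, 1) * p[1] + Amat(r, 2) * p[2] +
                 Atrans[r];
        double vx = (q[0] - morigin[0]) / mspacing[0];
        double vy = (q[1] - morigin[1]) / mspacing[1];
        double vz = (q[2] - morigin[2]) / mspacing[2];
        bool ok;
        double v = tri_sample_proxy(mv, mx, my, mz, vx, vy, vz, ok);
        out[x + (size_t)y * nx + (size_t)z * nx * ny] = ok ? v : fill;
      }
  out.attr("dim") = oshape;
  return out;
}
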