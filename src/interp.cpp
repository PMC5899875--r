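#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation helpers shared by the resampling and registration
// paths. All voxel coordinates are 0-based, node-centred: voxel (i,j,k) sits
// at physical origin + (i,j,k)*spacing.

static inline double tri_sample(const double *d, int nx, int ny, int nz,
                                double x, double y, double z, bool &ok) {
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

// [[Rcpp::export]]
NumericVector trilinear_sample_cpp(NumericVector data, IntegerVector shape,
                                   NumericMatrix pts, double fill) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double *d = data.begin();
  for (int i = 0; i < n; i++) {
    bool ok;
    double v = tri_sample(d, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2), ok);
    out[i] = ok ? v : fill;
  }
  return out;
}

static inline double lanczos_kernel(double x, int a) {
  if (x == 0.0) return 1.0;
  double ax = std::fabs(x);
  if (ax >= a) return 0.0;
  double px = M_PI * x;
  return a * std::sin(px) * std::sin(px / a) / (px * px);
}

// Separable Lanczos resampling along one axis of a 3D array. `ratio` is
// out_spacing / in_spacing; when > 1 (downsampling) the kernel is stretched
// by `ratio` as an antialiasing prefilter. Weights are renormalised per
// output sample so constants are reproduced exactly, including at borders.
// [[Rcpp::export]]
NumericVector lanczos_axis_cpp(NumericVector data, IntegerVector shape,
                               int axis, int n_out, double ratio, int a) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  int n_in = shape[axis];
  double r = ratio > 1.0 ? ratio : 1.0;
  int support = (int)std::ceil(a * r);
  int od[3] = {nx, ny, nz};
  od[axis] = n_out;
  NumericVector out((size_t)od[0] * od[1] * od[2]);
  // precompute weights per output index
  std::vector<std::vector<double> > wts(n_out);
  std::vector<int> i0(n_out);
  for (int j = 0; j < n_out; j++) {
    double c = j * ratio;
    int lo = (int)std::floor(c) - support;
    int hi = (int)std::ceil(c) + support;
    if (lo < 0) lo = 0;
    if (hi > n_in - 1) hi = n_in - 1;
    i0[j] = lo;
    double s = 0.0;
    std::vector<double> w(hi - lo + 1);
    for (int i = lo; i <= hi; i++) {
      double v = lanczos_kernel((i - c) / r, a);
      w[i - lo] = v;
      s += v;
    }
    if (s != 0.0)
      for (size_t k = 0; k < w.size(); k++) w[k] /= s;
    wts[j] = w;
  }
  const double *din = data.begin();
  double *dout = out.begin();
  size_t stride_in[3] = {1, (size_t)nx, (size_t)nx * ny};
  size_t stride_out[3] = {1, (size_t)od[0], (size_t)od[0] * od[1]};
  int o1 = (axis + 1) % 3, o2 = (axis + 2) % 3;
  int n1 = od[o1], n2 = od[o2];
  for (int b = 0; b < n2; b++) {
    for (int aIdx = 0; aIdx < n1; aIdx++) {
      size_t base_in = aIdx * stride_in[o1] + (size_t)b * stride_in[o2];
      size_t base_out = aIdx * stride_out[o1] + (size_t)b * stride_out[o2];
      for (int j = 0; j < n_out; j++) {
        const std::vector<double> &w = wts[j];
        size_t p = base_in + (size_t)i0[j] * stride_in[axis];
        double acc = 0.0;
        for (size_t k = 0; k < w.size(); k++)
          acc += w[k] * din[p + k * stride_in[axis]];
        dout[base_out + (size_t)j * stride_out[axis]] = acc;
      }
    }
  }
  return out;
}

// Separable 1D convolution along an axis with edge replication (used for the
// Gaussian pyramid of the multiscale schedules).
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector data, IntegerVector shape, int axis,
                            NumericVector kernel) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  int n = shape[axis];
  int kl = kernel.size();
  int kh = kl / 2;
  NumericVector out((size_t)nx * ny * nz);
  const double *din = data.begin();
  double *dout = out.begin();
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  int o1 = (axis + 1) % 3, o2 = (axis + 2) % 3;
  int n1 = shape[o1], n2 = shape[o2];
  for (int b = 0; b < n2; b++)
    for (int a = 0; a < n1; a++) {
      size_t base = a * stride[o1] + (size_t)b * stride[o2];
      for (int j = 0; j < n; j++) {
        double acc = 0;
        for (int k = 0; k < kl; k++) {
          int i = j + k - kh;
          if (i < 0) i = 0;
          if (i > n - 1) i = n - 1;
          acc += kernel[k] * din[base + (size_t)i * stride[axis]];
        }
        dout[base + (size_t)j * stride[axis]] = acc;
      }
    }
  out.attr("dim") = shape;
  return out;
}
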