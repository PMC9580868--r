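// Multi-scale 3D filter bank.
//
// All filters use symmetric (edge-included) mirror boundary handling on
// every axis. Separable filters are evaluated pass-by-pass (x, then y,
// then z); the pointwise evaluators replicate the pass nesting and
// accumulation order exactly, so sparse per-voxel features are
// bit-identical to the dense full-volume computation.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// filter kind codes shared with R (see R/feature_bank.R)
enum FilterKind {
  K_PIXEL = 0,
  K_GAUSSIAN = 1,
  K_MEAN = 2,
  K_MEDIAN = 3,
  K_MIN = 4,
  K_MAX = 5,
  K_RANGE = 6,
  K_STDDEV = 7,
  K_GRADMAG = 8,
  K_LOG = 9,
  K_DOG = 10,
  K_HESSMAX = 11
};

// symmetric mirror index: ...2,1,0,0,1,2,...,n-1,n-1,n-2,... (period 2n)
static inline int mirr(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * n;
  i %= p;
  if (i < 0) i += p;
  return (i < n) ? i : p - 1 - i;
}

static inline std::size_t lin(int x, int y, int z, int nx, int ny) {
  return (std::size_t)x + (std::size_t)nx * ((std::size_t)y + (std::size_t)ny * (std::size_t)z);
}

// truncated, normalized Gaussian taps of length k with sd sigma
static std::vector<double> gauss_taps(int k, double sigma) {
  const int r = k / 2;
  std::vector<double> w(k);
  double s = 0.0;
  for (int j = 0; j < k; ++j) {
    const double d = (double)(j - r);
    w[j] = std::exp(-0.5 * d * d / (sigma * sigma));
    s += w[j];
  }
  for (int j = 0; j < k; ++j) w[j] /= s;
  return w;
}

static std::vector<double> box_taps(int k) {
  return std::vector<double>(k, 1.0 / (double)k);
}

// ---- dense separable passes --------------------------------------------

// one weighted pass along `axis` (0=x,1=y,2=z)
static void sep_pass(const std::vector<double>& in, std::vector<double>& out,
                     int nx, int ny, int nz, int axis,
                     const std::vector<double>& w) {
  const int k = (int)w.size(), r = k / 2;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0.0;
        for (int j = 0; j < k; ++j) {
          int xx = x, yy = y, zz = z;
          if (axis == 0) xx = mirr(x + j - r, nx);
          else if (axis == 1) yy = mirr(y + j - r, ny);
          else zz = mirr(z + j - r, nz);
          s += w[j] * in[lin(xx, yy, zz, nx, ny)];
        }
        out[lin(x, y, z, nx, ny)] = s;
      }
}

static std::vector<double> sep_filter(const std::vector<double>& v,
                                      int nx, int ny, int nz,
                                      const std::vector<double>& w) {
  std::vector<double> a(v.size()), b(v.size());
  sep_pass(v, a, nx, ny, nz, 0, w);
  sep_pass(a, b, nx, ny, nz, 1, w);
  sep_pass(b, a, nx, ny, nz, 2, w);
  return a;
}

// one min/max pass along axis (box erosion/dilation is separable)
static void rank_pass(const std::vector<double>& in, std::vector<double>& out,
                      int nx, int ny, int nz, int axis, int k, bool take_max) {
  const int r = k / 2;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = take_max ? -std::numeric_limits<double>::infinity()
                            :  std::numeric_limits<double>::infinity();
        for (int j = 0; j < k; ++j) {
          int xx = x, yy = y, zz = z;
          if (axis == 0) xx = mirr(x + j - r, nx);
          else if (axis == 1) yy = mirr(y + j - r, ny);
          else zz = mirr(z + j - r, nz);
          const double val = in[lin(xx, yy, zz, nx, ny)];
          s = take_max ? std::max(s, val) : std::min(s, val);
        }
        out[lin(x, y, z, nx, ny)] = s;
      }
}

static std::vector<double> minmax_filter(const std::vector<double>& v,
                                         int nx, int ny, int nz, int k,
                                         bool take_max) {
  std::vector<double> a(v.size()), b(v.size());
  rank_pass(v, a, nx, ny, nz, 0, k, take_max);
  rank_pass(a, b, nx, ny, nz, 1, k, take_max);
  rank_pass(b, a, nx, ny, nz, 2, k, take_max);
  return a;
}

static std::vector<double> median_filter(const std::vector<double>& v,
                                         int nx, int ny, int nz, int k) {
  const int r = k / 2;
  const int K = k * k * k;
  std::vector<double> out(v.size());
  std::vector<double> buf(K);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int m = 0;
        for (int dz = -r; dz <= r; ++dz)
          for (int dy = -r; dy <= r; ++dy)
            for (int dx = -r; dx <= r; ++dx)
              buf[m++] = v[lin(mirr(x + dx, nx), mirr(y + dy, ny),
                               mirr(z + dz, nz), nx, ny)];
        std::nth_element(buf.begin(), buf.begin() + K / 2, buf.end());
        out[lin(x, y, z, nx, ny)] = buf[K / 2];
      }
  return out;
}

// ---- derived (Gaussian-chained) dense filters --------------------------

static std::vector<double> gradient_magnitude(const std::vector<double>& s,
                                              int nx, int ny, int nz) {
  std::vector<double> out(s.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double gx = (s[lin(mirr(x + 1, nx), y, z, nx, ny)] -
                           s[lin(mirr(x - 1, nx), y, z, nx, ny)]) / 2.0;
        const double gy = (s[lin(x, mirr(y + 1, ny), z, nx, ny)] -
                           s[lin(x, mirr(y - 1, ny), z, nx, ny)]) / 2.0;
        const double gz = (s[lin(x, y, mirr(z + 1, nz), nx, ny)] -
                           s[lin(x, y, mirr(z - 1, nz), nx, ny)]) / 2.0;
        out[lin(x, y, z, nx, ny)] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return out;
}

static std::vector<double> laplacian(const std::vector<double>& s,
                                     int nx, int ny, int nz) {
  std::vector<double> out(s.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double c = s[lin(x, y, z, nx, ny)];
        out[lin(x, y, z, nx, ny)] =
          s[lin(mirr(x + 1, nx), y, z, nx, ny)] +
          s[lin(mirr(x - 1, nx), y, z, nx, ny)] +
          s[lin(x, mirr(y + 1, ny), z, nx, ny)] +
          s[lin(x, mirr(y - 1, ny), z, nx, ny)] +
          s[lin(x, y, mirr(z + 1, nz), nx, ny)] +
          s[lin(x, y, mirr(z - 1, nz), nx, ny)] - 6.0 * c;
      }
  return out;
}

// largest eigenvalue of a symmetric 3x3 matrix (trigonometric method)
static double max_eigen_sym3(double a11, double a12, double a13,
                             double a22, double a23, double a33) {
  const double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) return std::max(a11, std::max(a22, a33));
  const double q = (a11 + a22 + a33) / 3.0;
  const double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                    (a33 - q) * (a33 - q) + 2.0 * p1;
  const double p = std::sqrt(p2 / 6.0);
  const double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
  const double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
  double detB = b11 * (b22 * b33 - b23 * b23) -
                b12 * (b12 * b33 - b23 * b13) +
                b13 * (b12 * b23 - b22 * b13);
  double rr = detB / 2.0;
  rr = std::max(-1.0, std::min(1.0, rr));
  const double phi = std::acos(rr) / 3.0;
  return q + 2.0 * p * std::cos(phi);
}

static std::vector<double> hessian_max(const std::vector<double>& s,
                                       int nx, int ny, int nz) {
  std::vector<double> out(s.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int xp = mirr(x + 1, nx), xm = mirr(x - 1, nx);
        const int yp = mirr(y + 1, ny), ym = mirr(y - 1, ny);
        const int zp = mirr(z + 1, nz), zm = mirr(z - 1, nz);
        const double c = s[lin(x, y, z, nx, ny)];
        const double dxx = s[lin(xp, y, z, nx, ny)] - 2.0 * c + s[lin(xm, y, z, nx, ny)];
        const double dyy = s[lin(x, yp, z, nx, ny)] - 2.0 * c + s[lin(x, ym, z, nx, ny)];
        const double dzz = s[lin(x, y, zp, nx, ny)] - 2.0 * c + s[lin(x, y, zm, nx, ny)];
        const double dxy = (s[lin(xp, yp, z, nx, ny)] - s[lin(xp, ym, z, nx, ny)] -
                            s[lin(xm, yp, z, nx, ny)] + s[lin(xm, ym, z, nx, ny)]) / 4.0;
        const double dxz = (s[lin(xp, y, zp, nx, ny)] - s[lin(xp, y, zm, nx, ny)] -
                            s[lin(xm, y, zp, nx, ny)] + s[lin(xm, y, zm, nx, ny)]) / 4.0;
        const double dyz = (s[lin(x, yp, zp, nx, ny)] - s[lin(x, yp, zm, nx, ny)] -
                            s[lin(x, ym, zp, nx, ny)] + s[lin(x, ym, zm, nx, ny)]) / 4.0;
        out[lin(x, y, z, nx, ny)] = max_eigen_sym3(dxx, dxy, dxz, dyy, dyz, dzz);
      }
  return out;
}

static std::vector<double> dense_filter(const std::vector<double>& v,
                                        int nx, int ny, int nz,
                                        int kind, int k) {
  const double sigma = (double)k / 6.0;
  switch (kind) {
    case K_PIXEL:
      return v;
    case K_GAUSSIAN:
      return sep_filter(v, nx, ny, nz, gauss_taps(k, sigma));
    case K_MEAN:
      return sep_filter(v, nx, ny, nz, box_taps(k));
    case K_MEDIAN:
      return median_filter(v, nx, ny, nz, k);
    case K_MIN:
      return minmax_filter(v, nx, ny, nz, k, false);
    case K_MAX:
      return minmax_filter(v, nx, ny, nz, k, true);
    case K_RANGE: {
      std::vector<double> lo = minmax_filter(v, nx, ny, nz, k, false);
      std::vector<double> hi = minmax_filter(v, nx, ny, nz, k, true);
      for (std::size_t i = 0; i < lo.size(); ++i) lo[i] = hi[i] - lo[i];
      return lo;
    }
    case K_STDDEV: {
      std::vector<double> v2(v.size());
      for (std::size_t i = 0; i < v.size(); ++i) v2[i] = v[i] * v[i];
      std::vector<double> m = sep_filter(v, nx, ny, nz, box_taps(k));
      std::vector<double> m2 = sep_filter(v2, nx, ny, nz, box_taps(k));
      for (std::size_t i = 0; i < m.size(); ++i) {
        const double var = m2[i] - m[i] * m[i];
        m[i] = std::sqrt(var > 0.0 ? var : 0.0);
      }
      return m;
    }
    case K_GRADMAG:
      return gradient_magnitude(sep_filter(v, nx, ny, nz, gauss_taps(k, sigma)), nx, ny, nz);
    case K_LOG:
      return laplacian(sep_filter(v, nx, ny, nz, gauss_taps(k, sigma)), nx, ny, nz);
    case K_DOG: {
      std::vector<double> s1 = sep_filter(v, nx, ny, nz, gauss_taps(k, sigma));
      std::vector<double> s2 = sep_filter(v, nx, ny, nz, gauss_taps(k, 2.0 * sigma));
      for (std::size_t i = 0; i < s1.size(); ++i) s1[i] -= s2[i];
      return s1;
    }
    case K_HESSMAX:
      return hessian_max(sep_filter(v, nx, ny, nz, gauss_taps(k, sigma)), nx, ny, nz);
    default:
      stop("unknown filter kind code %d", kind);
  }
  return v;  // not reached
}

// [[Rcpp::export]]
NumericVector cpp_filter_dense(NumericVector vol, IntegerVector dim,
                               int kind, int k) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  std::vector<double> out = dense_filter(v, nx, ny, nz, kind, k);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = dim;
  return res;
}

// ---- pointwise evaluation (bit-identical to the dense passes) ----------

// separable weighted sum at one voxel, nested z(y(x)) like the passes
static double point_sep(const std::vector<double>& v, int nx, int ny, int nz,
                        int x, int y, int z, const std::vector<double>& w) {
  const int k = (int)w.size(), r = k / 2;
  double sz = 0.0;
  for (int jz = 0; jz < k; ++jz) {
    const int zz = mirr(z + jz - r, nz);
    double sy = 0.0;
    for (int jy = 0; jy < k; ++jy) {
      const int yy = mirr(y + jy - r, ny);
      double sx = 0.0;
      for (int jx = 0; jx < k; ++jx)
        sx += w[jx] * v[lin(mirr(x + jx - r, nx), yy, zz, nx, ny)];
      sy += w[jy] * sx;
    }
    sz += w[jz] * sy;
  }
  return sz;
}

static double point_rank(const std::vector<double>& v, int nx, int ny, int nz,
                         int x, int y, int z, int k, int which) {
  // which: 0 min, 1 max, 2 median
  const int r = k / 2;
  if (which == 2) {
    const int K = k * k * k;
    std::vector<double> buf;
    buf.reserve(K);
    for (int dz = -r; dz <= r; ++dz)
      for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx)
          buf.push_back(v[lin(mirr(x + dx, nx), mirr(y + dy, ny),
                              mirr(z + dz, nz), nx, ny)]);
    std::nth_element(buf.begin(), buf.begin() + K / 2, buf.end());
    return buf[K / 2];
  }
  double s = (which == 1) ? -std::numeric_limits<double>::infinity()
                          :  std::numeric_limits<double>::infinity();
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx) {
        const double val = v[lin(mirr(x + dx, nx), mirr(y + dy, ny),
                                 mirr(z + dz, nz), nx, ny)];
        s = (which == 1) ? std::max(s, val) : std::min(s, val);
      }
  return s;
}

struct SmoothedProbe {
  // Gaussian-smoothed values at the center and its 18-neighborhood,
  // evaluated pointwise (identical to dense pass results)
  double c, xp, xm, yp, ym, zp, zm;
  double xpyp, xpym, xmyp, xmym;
  double xpzp, xpzm, xmzp, xmzm;
  double ypzp, ypzm, ymzp, ymzm;
};

static SmoothedProbe probe_smoothed(const std::vector<double>& v,
                                    int nx, int ny, int nz,
                                    int x, int y, int z,
                                    const std::vector<double>& w,
                                    bool need_mixed) {
  SmoothedProbe p;
  const int xp = mirr(x + 1, nx), xm = mirr(x - 1, nx);
  const int yp = mirr(y + 1, ny), ym = mirr(y - 1, ny);
  const int zp = mirr(z + 1, nz), zm = mirr(z - 1, nz);
  p.c = point_sep(v, nx, ny, nz, x, y, z, w);
  p.xp = point_sep(v, nx, ny, nz, xp, y, z, w);
  p.xm = point_sep(v, nx, ny, nz, xm, y, z, w);
  p.yp = point_sep(v, nx, ny, nz, x, yp, z, w);
  p.ym = point_sep(v, nx, ny, nz, x, ym, z, w);
  p.zp = point_sep(v, nx, ny, nz, x, y, zp, w);
  p.zm = point_sep(v, nx, ny, nz, x, y, zm, w);
  if (need_mixed) {
    p.xpyp = point_sep(v, nx, ny, nz, xp, yp, z, w);
    p.xpym = point_sep(v, nx, ny, nz, xp, ym, z, w);
    p.xmyp = point_sep(v, nx, ny, nz, xm, yp, z, w);
    p.xmym = point_sep(v, nx, ny, nz, xm, ym, z, w);
    p.xpzp = point_sep(v, nx, ny, nz, xp, y, zp, w);
    p.xpzm = point_sep(v, nx, ny, nz, xp, y, zm, w);
    p.xmzp = point_sep(v, nx, ny, nz, xm, y, zp, w);
    p.xmzm = point_sep(v, nx, ny, nz, xm, y, zm, w);
    p.ypzp = point_sep(v, nx, ny, nz, x, yp, zp, w);
    p.ypzm = point_sep(v, nx, ny, nz, x, yp, zm, w);
    p.ymzp = point_sep(v, nx, ny, nz, x, ym, zp, w);
    p.ymzm = point_sep(v, nx, ny, nz, x, ym, zm, w);
  }
  return p;
}

static double point_filter(const std::vector<double>& v, int nx, int ny, int nz,
                           int x, int y, int z, int kind, int k) {
  const double sigma = (double)k / 6.0;
  switch (kind) {
    case K_PIXEL:
      return v[lin(x, y, z, nx, ny)];
    case K_GAUSSIAN:
      return point_sep(v, nx, ny, nz, x, y, z, gauss_taps(k, sigma));
    case K_MEAN:
      return point_sep(v, nx, ny, nz, x, y, z, box_taps(k));
    case K_MEDIAN:
      return point_rank(v, nx, ny, nz, x, y, z, k, 2);
    case K_MIN:
      return point_rank(v, nx, ny, nz, x, y, z, k, 0);
    case K_MAX:
      return point_rank(v, nx, ny, nz, x, y, z, k, 1);
    case K_RANGE:
      return point_rank(v, nx, ny, nz, x, y, z, k, 1) -
             point_rank(v, nx, ny, nz, x, y, z, k, 0);
    case K_STDDEV: {
      // matches dense: box-mean of v and of v^2; v^2 materialized lazily
      const std::vector<double> w = box_taps(k);
      const int r = k / 2;
      double sz = 0.0, sz2 = 0.0;
      for (int jz = 0; jz < k; ++jz) {
        const int zz = mirr(z + jz - r, nz);
        double sy = 0.0, sy2 = 0.0;
        for (int jy = 0; jy < k; ++jy) {
          const int yy = mirr(y + jy - r, ny);
          double sx = 0.0, sx2 = 0.0;
          for (int jx = 0; jx < k; ++jx) {
            const double val = v[lin(mirr(x + jx - r, nx), yy, zz, nx, ny)];
            sx += w[jx] * val;
            sx2 += w[jx] * (val * val);
          }
          sy += w[jy] * sx;
          sy2 += w[jy] * sx2;
        }
        sz += w[jz] * sy;
        sz2 += w[jz] * sy2;
      }
      const double var = sz2 - sz * sz;
      return std::sqrt(var > 0.0 ? var : 0.0);
    }
    case K_GRADMAG: {
      const SmoothedProbe p =
        probe_smoothed(v, nx, ny, nz, x, y, z, gauss_taps(k, sigma), false);
      const double gx = (p.xp - p.xm) / 2.0;
      const double gy = (p.yp - p.ym) / 2.0;
      const double gz = (p.zp - p.zm) / 2.0;
      return std::sqrt(gx * gx + gy * gy + gz * gz);
    }
    case K_LOG: {
      const SmoothedProbe p =
        probe_smoothed(v, nx, ny, nz, x, y, z, gauss_taps(k, sigma), false);
      return p.xp + p.xm + p.yp + p.ym + p.zp + p.zm - 6.0 * p.c;
    }
    case K_DOG:
      return point_sep(v, nx, ny, nz, x, y, z, gauss_taps(k, sigma)) -
             point_sep(v, nx, ny, nz, x, y, z, gauss_taps(k, 2.0 * sigma));
    case K_HESSMAX: {
      const SmoothedProbe p =
        probe_smoothed(v, nx, ny, nz, x, y, z, gauss_taps(k, sigma), true);
      const double dxx = p.xp - 2.0 * p.c + p.xm;
      const double dyy = p.yp - 2.0 * p.c + p.ym;
      const double dzz = p.zp - 2.0 * p.c + p.zm;
      const double dxy = (p.xpyp - p.xpym - p.xmyp + p.xmym) / 4.0;
      const double dxz = (p.xpzp - p.xpzm - p.xmzp + p.xmzm) / 4.0;
      const double dyz = (p.ypzp - p.ypzm - p.ymzp + p.ymzm) / 4.0;
      return max_eigen_sym3(dxx, dxy, dxz, dyy, dyz, dzz);
    }
    default:
      stop("unknown filter kind code %d", kind);
  }
  return NA_REAL;  // not reached
}

// [[Rcpp::export]]
NumericMatrix cpp_features_at(NumericVector vol, IntegerVector dim,
                              IntegerVector ids0, IntegerVector kinds,
                              IntegerVector ks) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const std::size_t nvox = (std::size_t)nx * ny * nz;
  std::vector<double> v(vol.begin(), vol.end());
  const int n = ids0.size(), p = kinds.size();
  NumericMatrix out(n, p);
  for (int i = 0; i < n; ++i) {
    const long long id = ids0[i];
    if (id < 0 || (std::size_t)id >= nvox)
      stop("voxel id %lld out of bounds", id);
    const int x = (int)(id % nx);
    const int y = (int)((id / nx) % ny);
    const int z = (int)(id / ((long long)nx * ny));
    for (int j = 0; j < p; ++j)
      out(i, j) = point_filter(v, nx, ny, nz, x, y, z, kinds[j], ks[j]);
  }
  return out;
}
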