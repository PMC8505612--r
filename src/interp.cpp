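#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cubic B-spline interpolation with the standard recursive prefilter
// (single pole z = sqrt(3) - 2, mirror boundary). Coefficient lookups use
// mirror indexing; sample coordinates are clamped to the grid first, which
// gives nearest-edge replication for out-of-field voxels.

static inline int mirror_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * (n - 1);
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

static void prefilter_line(double *c, int n, int stride) {
  if (n < 2) return;
  const double z = std::sqrt(3.0) - 2.0;   // pole of the cubic B-spline
  const double gain = (1.0 - z) * (1.0 - 1.0 / z);
  for (int k = 0; k < n; ++k) c[k * stride] *= gain;
  // causal initialisation for mirror boundaries: truncated geometric sum
  // when the signal is longer than the decay horizon (tol 1e-12), the
  // exact mirror-periodic formula otherwise
  const int horizon =
      (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z)));
  double sum;
  if (horizon < n) {
    double zk = z;
    sum = c[0];
    for (int k = 1; k < horizon; ++k) {
      sum += zk * c[k * stride];
      zk *= z;
    }
  } else {
    const double iz = 1.0 / z;
    double zk = z;
    double z2n = std::pow(z, n - 1);
    sum = c[0] + z2n * c[(n - 1) * stride];
    z2n *= z2n * iz;            // z^(2n-3)
    for (int k = 1; k <= n - 2; ++k) {
      sum += (zk + z2n) * c[k * stride];
      zk *= z;
      z2n *= iz;
    }
    sum /= 1.0 - std::pow(z, 2 * n - 2);
  }
  c[0] = sum;
  for (int k = 1; k < n; ++k) c[k * stride] += z * c[(k - 1) * stride];
  c[(n - 1) * stride] =
      (z / (z * z - 1.0)) * (c[(n - 1) * stride] + z * c[(n - 2) * stride]);
  for (int k = n - 2; k >= 0; --k)
    c[k * stride] = z * (c[(k + 1) * stride] - c[k * stride]);
}

static void prefilter_volume(std::vector<double> &v, int nx, int ny, int nz) {
  // x lines
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      prefilter_line(&v[(size_t)z * nx * ny + (size_t)y * nx], nx, 1);
  // y lines
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      prefilter_line(&v[(size_t)z * nx * ny + x], ny, nx);
  // z lines
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      prefilter_line(&v[(size_t)y * nx + x], nz, nx * ny);
}

static inline void cubic_weights(double t, double *w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

static double sample_volume(const std::vector<double> &v, int nx, int ny,
                            int nz, double x, double y, double z, int order) {
  // clamp: nearest-edge replication outside the grid
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  const size_t sy = nx, sz = (size_t)nx * ny;
  if (order == 0) {
    int ix = (int)std::lround(x), iy = (int)std::lround(y),
        iz = (int)std::lround(z);
    return v[(size_t)iz * sz + (size_t)iy * sy + ix];
  }
  if (order == 1) {
    int ix = (int)std::floor(x), iy = (int)std::floor(y),
        iz = (int)std::floor(z);
    if (ix > nx - 2) ix = nx > 1 ? nx - 2 : 0;
    if (iy > ny - 2) iy = ny > 1 ? ny - 2 : 0;
    if (iz > nz - 2) iz = nz > 1 ? nz - 2 : 0;
    double tx = x - ix, ty = y - iy, tz = z - iz;
    double acc = 0.0;
    for (int c = 0; c < 2; ++c)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a) {
          double w = (a ? tx : 1 - tx) * (b ? ty : 1 - ty) * (c ? tz : 1 - tz);
          acc += w * v[(size_t)mirror_index(iz + c, nz) * sz +
                       (size_t)mirror_index(iy + b, ny) * sy +
                       mirror_index(ix + a, nx)];
        }
    return acc;
  }
  // order 3
  int ix = (int)std::floor(x), iy = (int)std::floor(y),
      iz = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  cubic_weights(x - ix, wx);
  cubic_weights(y - iy, wy);
  cubic_weights(z - iz, wz);
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) {
    const size_t oz = (size_t)mirror_index(iz - 1 + c, nz) * sz;
    for (int b = 0; b < 4; ++b) {
      const size_t oy = oz + (size_t)mirror_index(iy - 1 + b, ny) * sy;
      const double wyz = wy[b] * wz[c];
      double row = 0.0;
      for (int a = 0; a < 4; ++a)
        row += wx[a] * v[oy + mirror_index(ix - 1 + a, nx)];
      acc += wyz * row;
    }
  }
  return acc;
}

// Resample through an affine index map: output voxel o (0-based) reads the
// input at index coordinates A %*% o + b.  order: 0 nearest, 1 trilinear,
// 3 cubic B-spline (with prefilter).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dim,
                                  NumericMatrix A, NumericVector b,
                                  IntegerVector outDim, int order) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = outDim[0], my = outDim[1], mz = outDim[2];
  std::vector<double> v(vol.begin(), vol.end());
  if (order == 3) prefilter_volume(v, nx, ny, nz);
  NumericVector out((size_t)mx * my * mz);
  size_t idx = 0;
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x, ++idx) {
        const double sx = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + b[0];
        const double sy = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + b[1];
        const double sz = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + b[2];
        out[idx] = sample_volume(v, nx, ny, nz, sx, sy, sz, order);
      }
  return out;
}
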