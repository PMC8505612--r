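#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Gamma-index map between two feature maps on a common grid.
// For each in-mask reference voxel v,
//   Gamma(v) = min_u sqrt( ||u - v||^2 / DTA^2 + (F_eval(u) - F_ref(v))^2 / dF^2 )
// where u runs over a sub-voxel lattice (trilinear upsampling of the eval
// map by `factor`) within `searchCap` mm of v.  Candidate offsets are
// visited in increasing distance so the search can stop as soon as the
// distance term alone exceeds the current best.

struct Offset {
  int dx, dy, dz;
  double d2mm;
};

// [[Rcpp::export]]
NumericVector cpp_gamma_map(NumericVector ref, NumericVector eval,
                            LogicalVector mask, IntegerVector dim,
                            NumericVector spacing, double dtaMm,
                            double deltaF, double searchCapMm, int factor) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t sy = nx, sz = (size_t)nx * ny;

  // upsampled eval lattice: (n-1)*factor + 1 samples per axis; NaN where any
  // corner of the trilinear support is NaN (outside the eval map's domain)
  const int ux = (nx - 1) * factor + 1, uy = (ny - 1) * factor + 1,
            uz = (nz - 1) * factor + 1;
  const size_t usy = ux, usz = (size_t)ux * uy;
  std::vector<double> U((size_t)ux * uy * uz);
  for (int c = 0; c < uz; ++c) {
    const int z0 = c / factor, fz = c % factor;
    const double tz = (double)fz / factor;
    for (int b = 0; b < uy; ++b) {
      const int y0 = b / factor, fy = b % factor;
      const double ty = (double)fy / factor;
      for (int a = 0; a < ux; ++a) {
        const int x0 = a / factor, fx = a % factor;
        const double tx = (double)fx / factor;
        double acc = 0.0;
        bool ok = true;
        for (int kz = 0; kz <= (fz ? 1 : 0) && ok; ++kz)
          for (int ky = 0; ky <= (fy ? 1 : 0) && ok; ++ky)
            for (int kx = 0; kx <= (fx ? 1 : 0) && ok; ++kx) {
              const double w = (kx ? tx : (fx ? 1 - tx : 1)) *
                               (ky ? ty : (fy ? 1 - ty : 1)) *
                               (kz ? tz : (fz ? 1 - tz : 1));
              const double v =
                  eval[(size_t)(z0 + kz) * sz + (size_t)(y0 + ky) * sy +
                       (x0 + kx)];
              if (ISNAN(v)) { ok = false; break; }
              acc += w * v;
            }
        U[(size_t)c * usz + (size_t)b * usy + a] =
            ok ? acc : NA_REAL;
      }
    }
  }

  // candidate offsets on the fine lattice, sorted by physical distance
  const double hx = spacing[0] / factor, hy = spacing[1] / factor,
               hz = spacing[2] / factor;
  const int rx = (int)std::floor(searchCapMm / hx),
            ry = (int)std::floor(searchCapMm / hy),
            rz = (int)std::floor(searchCapMm / hz);
  const double cap2 = searchCapMm * searchCapMm;
  std::vector<Offset> offs;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        const double d2 =
            dx * hx * dx * hx + dy * hy * dy * hy + dz * hz * dz * hz;
        if (d2 <= cap2) offs.push_back({dx, dy, dz, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.d2mm < b.d2mm; });

  const double dta2 = dtaMm * dtaMm, df2 = deltaF * deltaF;
  NumericVector out((size_t)nx * ny * nz, NA_REAL);
  size_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        if (!mask[idx] || ISNAN(ref[idx])) continue;
        const double rv = ref[idx];
        const int cx = x * factor, cy = y * factor, cz = z * factor;
        double best = R_PosInf;
        bool found = false;
        for (const Offset &o : offs) {
          const double dterm = o.d2mm / dta2;
          if (dterm >= best) break;
          const int a = cx + o.dx, b = cy + o.dy, c = cz + o.dz;
          if (a < 0 || a >= ux || b < 0 || b >= uy || c < 0 || c >= uz)
            continue;
          const double ev = U[(size_t)c * usz + (size_t)b * usy + a];
          if (ISNAN(ev)) continue;
          const double g2 = dterm + (ev - rv) * (ev - rv) / df2;
          if (g2 < best) best = g2;
          found = true;
        }
        if (found) out[idx] = std::sqrt(best);
      }
  return out;
}
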