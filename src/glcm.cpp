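#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel-wise GLCM texture maps.  For every in-mask voxel a symmetric GLCM is
// accumulated over the cubic kernel of edge 2R+1 (clipped to the crop), one
// matrix per direction offset; the 23 features are evaluated per direction
// and averaged over directions that contain at least one voxel pair.
//
// Feature order (alphabetical, fixed; must match glcmFeatureNames() in R):
//  0 Autocorrelation  1 ClusterProminence  2 ClusterShade  3 ClusterTendency
//  4 Contrast  5 Correlation  6 DifferenceAverage  7 DifferenceEntropy
//  8 DifferenceVariance  9 Id  10 Idm  11 Idmn  12 Idn  13 Imc1  14 Imc2
// 15 InverseVariance  16 JointAverage  17 JointEnergy  18 JointEntropy
// 19 MaximumProbability  20 SumAverage  21 SumEntropy  22 SumSquares

static const double EPS = 2.2e-16;

static inline double log2e(double x) { return std::log2(x + EPS); }

// p: ng x ng joint probabilities (column-major), already normalised.
static void features_from_p(const double *p, int ng, double *f,
                            std::vector<double> &px, std::vector<double> &py,
                            std::vector<double> &psum,
                            std::vector<double> &pdiff) {
  std::fill(px.begin(), px.begin() + ng, 0.0);
  std::fill(py.begin(), py.begin() + ng, 0.0);
  std::fill(psum.begin(), psum.begin() + 2 * ng + 1, 0.0);
  std::fill(pdiff.begin(), pdiff.begin() + ng, 0.0);

  double autoc = 0, contrast = 0, energy = 0, entropy = 0, maxp = 0;
  double id = 0, idm = 0, idmn = 0, idn = 0;
  const double ngd = (double)ng;
  for (int j = 0; j < ng; ++j) {
    for (int i = 0; i < ng; ++i) {
      const double pij = p[i + j * ng];
      if (pij == 0.0) continue;
      px[i] += pij;
      py[j] += pij;
      psum[i + j + 2] += pij;
      const int d = i >= j ? i - j : j - i;
      pdiff[d] += pij;
      autoc += pij * (i + 1) * (j + 1);
      contrast += pij * d * d;
      energy += pij * pij;
      entropy -= pij * log2e(pij);
      if (pij > maxp) maxp = pij;
      id += pij / (1.0 + d);
      idm += pij / (1.0 + (double)d * d);
      idn += pij / (1.0 + d / ngd);
      idmn += pij / (1.0 + (double)d * d / (ngd * ngd));
    }
  }

  double mux = 0, muy = 0, hx = 0, hy = 0;
  for (int i = 0; i < ng; ++i) {
    mux += (i + 1) * px[i];
    muy += (i + 1) * py[i];
    if (px[i] > 0) hx -= px[i] * log2e(px[i]);
    if (py[i] > 0) hy -= py[i] * log2e(py[i]);
  }
  double sx2 = 0, sy2 = 0;
  for (int i = 0; i < ng; ++i) {
    sx2 += (i + 1 - mux) * (i + 1 - mux) * px[i];
    sy2 += (i + 1 - muy) * (i + 1 - muy) * py[i];
  }

  double hxy1 = 0, hxy2 = 0, cshade = 0, cprom = 0, ctend = 0;
  for (int j = 0; j < ng; ++j) {
    for (int i = 0; i < ng; ++i) {
      const double pij = p[i + j * ng];
      const double pp = px[i] * py[j];
      if (pp > 0) hxy2 -= pp * log2e(pp);
      if (pij > 0) {
        hxy1 -= pij * log2e(pp);
        const double c = (i + 1) + (j + 1) - mux - muy;
        const double c2 = c * c;
        ctend += c2 * pij;
        cshade += c2 * c * pij;
        cprom += c2 * c2 * pij;
      }
    }
  }

  double sumavg = 0, sument = 0;
  for (int k = 2; k <= 2 * ng; ++k) {
    const double q = psum[k];
    if (q > 0) {
      sumavg += k * q;
      sument -= q * log2e(q);
    }
  }
  double diffavg = 0, diffent = 0, invvar = 0;
  for (int k = 0; k < ng; ++k) {
    const double q = pdiff[k];
    if (q > 0) {
      diffavg += k * q;
      diffent -= q * log2e(q);
      if (k > 0) invvar += q / ((double)k * k);
    }
  }
  double diffvar = 0;
  for (int k = 0; k < ng; ++k)
    if (pdiff[k] > 0) diffvar += (k - diffavg) * (k - diffavg) * pdiff[k];

  const double ss = sx2 * sy2;
  const double corr = ss > EPS ? (autoc - mux * muy) / std::sqrt(ss) : 1.0;
  const double hmax = hx > hy ? hx : hy;
  const double imc1 = hmax > 0 ? (entropy - hxy1) / hmax : 0.0;
  double i2 = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
  const double imc2 = std::sqrt(i2 > 0 ? i2 : 0.0);

  f[0] = autoc;
  f[1] = cprom;
  f[2] = cshade;
  f[3] = ctend;
  f[4] = contrast;
  f[5] = corr;
  f[6] = diffavg;
  f[7] = diffent;
  f[8] = diffvar;
  f[9] = id;
  f[10] = idm;
  f[11] = idmn;
  f[12] = idn;
  f[13] = imc1;
  f[14] = imc2;
  f[15] = invvar;
  f[16] = mux;
  f[17] = energy;
  f[18] = entropy;
  f[19] = maxp;
  f[20] = sumavg;
  f[21] = sument;
  f[22] = sx2;  // SumSquares = variance of the gray-level marginal
}

// gray: bin indices 1..ng over the whole crop; mask: logical; dirs: 13 x 3
// integer offsets.  Returns an nMask x 23 matrix in raster (column-major)
// order of the in-mask voxels.
// [[Rcpp::export]]
NumericMatrix cpp_feature_maps(IntegerVector gray, LogicalVector mask,
                               IntegerVector dim, int ng, IntegerMatrix dirs,
                               int radius, int dist, bool maskedKernel) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t sy = nx, sz = (size_t)nx * ny;
  const int ndir = dirs.nrow();
  size_t nmask = 0;
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    if (mask[i]) ++nmask;
  NumericMatrix out(nmask, 23);

  std::vector<double> p((size_t)ng * ng), px(ng), py(ng), psum(2 * ng + 1),
      pdiff(ng);
  std::vector<double> fdir(23), facc(23);

  size_t row = 0, idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        if (!mask[idx]) continue;
        const int x0 = std::max(0, x - radius), x1 = std::min(nx - 1, x + radius);
        const int y0 = std::max(0, y - radius), y1 = std::min(ny - 1, y + radius);
        const int z0 = std::max(0, z - radius), z1 = std::min(nz - 1, z + radius);
        std::fill(facc.begin(), facc.end(), 0.0);
        int ndone = 0;
        for (int d = 0; d < ndir; ++d) {
          const int dx = dirs(d, 0) * dist, dy = dirs(d, 1) * dist,
                    dz = dirs(d, 2) * dist;
          std::fill(p.begin(), p.end(), 0.0);
          double npair = 0;
          for (int c = z0; c <= z1; ++c) {
            const int cc = c + dz;
            if (cc < z0 || cc > z1) continue;
            for (int b = y0; b <= y1; ++b) {
              const int bb = b + dy;
              if (bb < y0 || bb > y1) continue;
              for (int a = x0; a <= x1; ++a) {
                const int aa = a + dx;
                if (aa < x0 || aa > x1) continue;
                const size_t ia = (size_t)c * sz + (size_t)b * sy + a;
                const size_t ib = (size_t)cc * sz + (size_t)bb * sy + aa;
                if (maskedKernel && (!mask[ia] || !mask[ib])) continue;
                const int ga = gray[ia] - 1, gb = gray[ib] - 1;
                p[ga + (size_t)gb * ng] += 1.0;
                p[gb + (size_t)ga * ng] += 1.0;
                npair += 1.0;
              }
            }
          }
          if (npair == 0) continue;
          const double tot = 2.0 * npair;
          for (size_t k = 0; k < p.size(); ++k) p[k] /= tot;
          features_from_p(p.data(), ng, fdir.data(), px, py, psum, pdiff);
          for (int k = 0; k < 23; ++k) facc[k] += fdir[k];
          ++ndone;
        }
        if (ndone > 0)
          for (int k = 0; k < 23; ++k) out(row, k) = facc[k] / ndone;
        ++row;
      }
  return out;
}
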