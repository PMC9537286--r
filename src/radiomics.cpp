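// Low-level kernels for the radiomics stack: separable convolution with
// mirror padding, affine resampling (tricubic Catmull-Rom / trilinear),
// grey-level zone/run/co-occurrence enumeration, exact Euclidean distance
// transform and intensity-peak search.  All arrays are column-major
// (R layout), 0-based internally.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

static inline int mirror_idx(int i, int n) {
  // reflect without edge duplication ("mirror"); period 2n-2
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i = i % period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

// [[Rcpp::export(name = ".conv1dAxis")]]
NumericVector conv1d_axis(NumericVector arr, IntegerVector dim,
                          NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size(), r = (kl - 1) / 2;
  NumericVector out(arr.size());
  const int n_axis = dim[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        const int pos = (axis == 0) ? i : (axis == 1 ? j : k);
        for (int t = 0; t < kl; ++t) {
          const int q = mirror_idx(pos + t - r, n_axis);
          int ii = i, jj = j, kk = k;
          if (axis == 0) ii = q; else if (axis == 1) jj = q; else kk = q;
          acc += kernel[t] * arr[ii + (size_t)nx * (jj + (size_t)ny * kk)];
        }
        out[i + (size_t)nx * (j + (size_t)ny * k)] = acc;
      }
  return out;
}

static inline double fetch(const NumericVector &a, const IntegerVector &d,
                           int i, int j, int k) {
  return a[mirror_idx(i, d[0]) +
           (size_t)d[0] * (mirror_idx(j, d[1]) +
                           (size_t)d[1] * mirror_idx(k, d[2]))];
}

static inline void cr_weights(double u, double w[4]) {
  // Catmull-Rom cubic convolution weights for fractional offset u in [0,1)
  const double u2 = u * u, u3 = u2 * u;
  w[0] = 0.5 * (-u3 + 2.0 * u2 - u);
  w[1] = 0.5 * (3.0 * u3 - 5.0 * u2 + 2.0);
  w[2] = 0.5 * (-3.0 * u3 + 4.0 * u2 + u);
  w[3] = 0.5 * (u3 - u2);
}

// p_in = M %*% p_out + t (0-based voxel coordinates)
// [[Rcpp::export(name = ".affineResample")]]
NumericVector affine_resample(NumericVector arr, IntegerVector dimIn,
                              IntegerVector dimOut, NumericMatrix M,
                              NumericVector t, std::string method) {
  const int nx = dimOut[0], ny = dimOut[1], nz = dimOut[2];
  NumericVector out((size_t)nx * ny * nz);
  const bool cubic = (method == "cubic");
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double x = M(0, 0) * i + M(0, 1) * j + M(0, 2) * k + t[0];
        const double y = M(1, 0) * i + M(1, 1) * j + M(1, 2) * k + t[1];
        const double z = M(2, 0) * i + M(2, 1) * j + M(2, 2) * k + t[2];
        const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                  z0 = (int)std::floor(z);
        const double ux = x - x0, uy = y - y0, uz = z - z0;
        double val = 0.0;
        if (cubic) {
          double wx[4], wy[4], wz[4];
          cr_weights(ux, wx); cr_weights(uy, wy); cr_weights(uz, wz);
          for (int c = 0; c < 4; ++c)
            for (int b = 0; b < 4; ++b)
              for (int a = 0; a < 4; ++a)
                val += wx[a] * wy[b] * wz[c] *
                       fetch(arr, dimIn, x0 - 1 + a, y0 - 1 + b, z0 - 1 + c);
        } else {
          for (int c = 0; c < 2; ++c)
            for (int b = 0; b < 2; ++b)
              for (int a = 0; a < 2; ++a) {
                const double w = (a ? ux : 1 - ux) * (b ? uy : 1 - uy) *
                                 (c ? uz : 1 - uz);
                if (w > 0)
                  val += w * fetch(arr, dimIn, x0 + a, y0 + b, z0 + c);
              }
        }
        out[i + (size_t)nx * (j + (size_t)ny * k)] = val;
      }
  return out;
}

// Zones of identical grey level, 26-connectivity.  vol: discretised levels,
// NA_INTEGER outside the intensity mask.  Returns matrix (level, size).
// [[Rcpp::export(name = ".glszmZones")]]
IntegerMatrix glszm_zones(IntegerVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> seen((size_t)nx * ny * nz, 0);
  std::vector<std::pair<int, int> > zones;
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
        if (seen[idx] || vol[idx] == NA_INTEGER) continue;
        const int lev = vol[idx];
        int size = 0;
        stack.clear();
        stack.push_back((int)idx);
        seen[idx] = 1;
        while (!stack.empty()) {
          const int cur = stack.back();
          stack.pop_back();
          ++size;
          const int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (!di && !dj && !dk) continue;
                const int ii = ci + di, jj = cj + dj, kk = ck + dk;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                    kk >= nz)
                  continue;
                const size_t nb = ii + (size_t)nx * (jj + (size_t)ny * kk);
                if (!seen[nb] && vol[nb] == lev) {
                  seen[nb] = 1;
                  stack.push_back((int)nb);
                }
              }
        }
        zones.push_back(std::make_pair(lev, size));
      }
  IntegerMatrix out(zones.size(), 2);
  for (size_t z = 0; z < zones.size(); ++z) {
    out(z, 0) = zones[z].first;
    out(z, 1) = zones[z].second;
  }
  return out;
}

static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {1, 1, 0}, {1, -1, 0}, {1, 0, 1},
  {1, 0, -1}, {0, 1, 1}, {0, 1, -1}, {1, 1, 1}, {1, 1, -1}, {1, -1, 1},
  {1, -1, -1}};

// Symmetric co-occurrence counts, distance 1, one matrix per direction.
// [[Rcpp::export(name = ".glcmCounts")]]
List glcm_counts(IntegerVector vol, IntegerVector dim, int nLevels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  List out(13);
  for (int d = 0; d < 13; ++d) {
    IntegerMatrix m(nLevels, nLevels);
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
          if (vol[idx] == NA_INTEGER) continue;
          const int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          const size_t nb = ii + (size_t)nx * (jj + (size_t)ny * kk);
          if (vol[nb] == NA_INTEGER) continue;
          m(vol[idx] - 1, vol[nb] - 1) += 1;
          m(vol[nb] - 1, vol[idx] - 1) += 1;
        }
    out[d] = m;
  }
  return out;
}

// Run-length counts (level x run length), one matrix per direction.
// [[Rcpp::export(name = ".glrlmCounts")]]
List glrlm_counts(IntegerVector vol, IntegerVector dim, int nLevels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  List out(13);
  const int maxLen = std::max(std::max(nx, ny), nz);
  for (int d = 0; d < 13; ++d) {
    IntegerMatrix m(nLevels, maxLen);
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
          if (vol[idx] == NA_INTEGER) continue;
          const int lev = vol[idx];
          // run start: predecessor out of grid / mask / different level
          const int pi = i - dx, pj = j - dy, pk = k - dz;
          if (pi >= 0 && pj >= 0 && pk >= 0 && pi < nx && pj < ny && pk < nz) {
            const size_t pb = pi + (size_t)nx * (pj + (size_t)ny * pk);
            if (vol[pb] == lev) continue;
          }
          int len = 1;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          while (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny &&
                 kk < nz &&
                 vol[ii + (size_t)nx * (jj + (size_t)ny * kk)] == lev) {
            ++len;
            ii += dx; jj += dy; kk += dz;
          }
          m(lev - 1, len - 1) += 1;
        }
    out[d] = m;
  }
  return out;
}

static void edt_1d(std::vector<double> &f, std::vector<double> &d,
                   std::vector<int> &v, std::vector<double> &z, int n,
                   double step) {
  // Felzenszwalb & Huttenlocher lower-envelope 1D squared EDT
  const double INF = std::numeric_limits<double>::infinity();
  int q = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  const double s2 = step * step;
  for (int i = 1; i < n; ++i) {
    double s;
    while (true) {
      s = ((f[i] + s2 * i * i) - (f[v[q]] + s2 * v[q] * v[q])) /
          (2.0 * s2 * (i - v[q]));
      if (s <= z[q]) { --q; } else break;
    }
    ++q;
    v[q] = i; z[q] = s; z[q + 1] = INF;
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    while (z[q + 1] < i) ++q;
    d[i] = s2 * (i - v[q]) * (i - v[q]) + f[v[q]];
  }
}

// Squared Euclidean distance (mm^2) to the nearest "feature" voxel
// (mask != 0), anisotropic spacing.
// [[Rcpp::export(name = ".edtSquared")]]
NumericVector edt_squared(IntegerVector mask, IntegerVector dim,
                          NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel keeps the lower-envelope arithmetic NaN-free
  const double FAR = 1e20;
  std::vector<double> g((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); ++i) g[i] = mask[i] ? 0.0 : FAR;
  const int nmax = std::max(std::max(nx, ny), nz);
  std::vector<double> f(nmax), dcol(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = g[i + (size_t)nx * (j + (size_t)ny * k)];
      edt_1d(f, dcol, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) g[i + (size_t)nx * (j + (size_t)ny * k)] = dcol[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[i + (size_t)nx * (j + (size_t)ny * k)];
      edt_1d(f, dcol, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) g[i + (size_t)nx * (j + (size_t)ny * k)] = dcol[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[i + (size_t)nx * (j + (size_t)ny * k)];
      edt_1d(f, dcol, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) g[i + (size_t)nx * (j + (size_t)ny * k)] = dcol[k];
    }
  NumericVector out(g.size());
  for (size_t i = 0; i < g.size(); ++i) out[i] = g[i];
  return out;
}

// Largest Euclidean distance between any two points (rows, mm coords).
// [[Rcpp::export(name = ".maxPairDist")]]
double max_pair_dist(NumericMatrix pts) {
  double best = 0.0;
  const int n = pts.nrow();
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      const double dx = pts(a, 0) - pts(b, 0), dy = pts(a, 1) - pts(b, 1),
                   dz = pts(a, 2) - pts(b, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}

// Spherical-neighbourhood mean intensity around every in-mask voxel;
// returns (localPeak, globalPeak).  offsets: precomputed voxel offsets of
// the 1 cm^3 sphere (rows: di, dj, dk).
// [[Rcpp::export(name = ".intensityPeaks")]]
NumericVector intensity_peaks(NumericVector vol, IntegerVector dim,
                              IntegerVector mask, IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double globalPeak = -std::numeric_limits<double>::infinity();
  double maxI = -std::numeric_limits<double>::infinity();
  double localPeak = -std::numeric_limits<double>::infinity();
  const int no = offsets.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
        if (!mask[idx]) continue;
        double acc = 0.0;
        int cnt = 0;
        for (int o = 0; o < no; ++o) {
          const int ii = i + offsets(o, 0), jj = j + offsets(o, 1),
                    kk = k + offsets(o, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          acc += vol[ii + (size_t)nx * (jj + (size_t)ny * kk)];
          ++cnt;
        }
        const double sph = cnt ? acc / cnt : vol[idx];
        if (sph > globalPeak) globalPeak = sph;
        if (vol[idx] > maxI || (vol[idx] == maxI && sph > localPeak)) {
          if (vol[idx] > maxI) localPeak = sph;
          else localPeak = std::max(localPeak, sph);
          maxI = std::max(maxI, vol[idx]);
        }
      }
  return NumericVector::create(localPeak, globalPeak);
}
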