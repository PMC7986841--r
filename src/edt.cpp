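// Exact Euclidean distance transform on a 3D voxel grid via the
// separable lower-envelope-of-parabolas algorithm (three 1D passes).
// Input: logical seed mask; output: distance in voxel units from every
// voxel centre to the nearest seed voxel centre.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform of sampled function f (Felzenszwalb-
// Huttenlocher); d[q] = min_p (q - p)^2 + f[p].
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  int n = (int)f.size();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { std::fill(d.begin(), d.end(), INF); return; }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = q0; z[0] = -INF; z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = q - (double)v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export(name = ".edt")]]
NumericVector edt(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<double> D(N);
  for (R_xlen_t i = 0; i < N; ++i) D[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = D[base + x];
      dt1d(f, d);
      for (int x = 0; x < nx; ++x) D[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = D[base + (R_xlen_t)y * nx];
      dt1d(f, d);
      for (int y = 0; y < ny; ++y) D[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = D[base + (R_xlen_t)z * sz];
      dt1d(f, d);
      for (int z = 0; z < nz; ++z) D[base + (R_xlen_t)z * sz] = d[z];
    }

  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i)
    out[i] = (D[i] == INF) ? NA_REAL : std::sqrt(D[i]);
  return out;
}
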