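#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D lower-envelope passes with anisotropic voxel spacing in mm.

namespace {

const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform of sampled function f at positions i*w;
// INF samples carry no parabola.
void dt1d(const std::vector<double> &f, std::vector<double> &d, double w,
          std::vector<int> &v, std::vector<double> &zb) {
  const int n = (int)f.size();
  const double w2 = w * w;
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= zb[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

} // namespace

// Squared distance (mm^2) from every voxel center to the nearest true voxel
// center. All-false input gives Inf everywhere.
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  const int *m = LOGICAL(mask);
  for (size_t i = 0; i < n; ++i) out[i] = m[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  auto idx = [&](int x, int y, int z) -> size_t {
    return x + (size_t)nx * (y + (size_t)ny * z);
  };

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = out[idx(x, y, z)];
      f.resize(nx); d.resize(nx);
      dt1d(f, d, spacing[0], v, zb);
      for (int x = 0; x < nx; ++x) out[idx(x, y, z)] = d[x];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[idx(x, y, z)];
      f.resize(ny); d.resize(ny);
      dt1d(f, d, spacing[1], v, zb);
      for (int y = 0; y < ny; ++y) out[idx(x, y, z)] = d[y];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[idx(x, y, z)];
      f.resize(nz); d.resize(nz);
      dt1d(f, d, spacing[2], v, zb);
      for (int z = 0; z < nz; ++z) out[idx(x, y, z)] = d[z];
      f.resize(nmax); d.resize(nmax);
    }

  out.attr("dim") = dim;
  return out;
}
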