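#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform on an anisotropic rectilinear lattice,
// computed by three 1-D lower-envelope passes over squared distances
// (Felzenszwalb & Huttenlocher). Returns, for every voxel, the distance in mm
// to the nearest TRUE voxel (0 inside the set).

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, double s2) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INFINITY) continue;
    while (true) {
      if (f[v[k]] == INFINITY) { // first finite sample
        if (k == 0) { v[0] = q; z[0] = -INFINITY; z[1] = INFINITY; break; }
        --k;
        continue;
      }
      double s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k]))
               / (2.0 * s2 * q - 2.0 * s2 * v[k]);
      if (s <= z[k]) { --k; continue; }
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INFINITY;
      break;
    }
  }
  if (f[v[0]] == INFINITY) { // no finite samples at all
    for (int q = 0; q < n; ++q) d[q] = INFINITY;
    return;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = (double)(q - v[kk]);
    d[q] = s2 * dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  const double sx = spacing[0], sy = spacing[1], sz = spacing.size() > 2 ? spacing[2] : 1.0;
  const size_t N = (size_t)nx * ny * nz;
  std::vector<double> g(N);
  const int *M = LOGICAL(mask);
  for (size_t i = 0; i < N; ++i) g[i] = M[i] ? 0.0 : INFINITY;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t off = (size_t)j * nx + (size_t)k * nx * ny;
      f.assign(g.begin() + off, g.begin() + off + nx);
      dt1d(f, d, v, z, sx * sx);
      for (int i = 0; i < nx; ++i) g[off + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t off = (size_t)i + (size_t)k * nx * ny;
      for (int j = 0; j < ny; ++j) f[j] = g[off + (size_t)j * nx];
      f.resize(ny);
      dt1d(f, d, v, z, sy * sy);
      for (int j = 0; j < ny; ++j) g[off + (size_t)j * nx] = d[j];
      f.resize(nmax);
    }
  // z pass
  if (nz > 1)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t off = (size_t)i + (size_t)j * nx;
        for (int k = 0; k < nz; ++k) f[k] = g[off + (size_t)k * nx * ny];
        f.resize(nz);
        dt1d(f, d, v, z, sz * sz);
        for (int k = 0; k < nz; ++k) g[off + (size_t)k * nx * ny] = d[k];
        f.resize(nmax);
      }

  NumericVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = std::sqrt(g[i]);
  return out;
}
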