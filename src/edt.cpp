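#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable per axis, with per-axis physical spacing so the metric is
// anisotropic in voxel units but Euclidean in mm.

namespace {

// Large finite stand-in for +infinity: keeps the parabola-intersection
// arithmetic NaN-free when whole scanlines are empty.
const double INF = 1e20;

// 1D squared-distance transform of sampled function f at spacing h.
void dt1d(std::vector<double> &f, double h, std::vector<double> &d,
          std::vector<int> &v, std::vector<double> &z) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double)q * h, vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    double diff = qq - (double)v[k] * h;
    d[q] = diff * diff + f[v[k]];
  }
}

} // namespace

// Squared distance (mm^2) from every voxel to the nearest TRUE voxel of
// `mask` (dims `dm`, spacing `sp`). Voxels outside the array are ignored.
// Returns +Inf where the mask is empty.
// [[Rcpp::export(name = ".edtSquared")]]
NumericVector edtSquared(LogicalVector mask, IntegerVector dm,
                         NumericVector sp) {
  const int nd = dm.size();
  if (nd != 3) stop("edtSquared expects 3 dimensions");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int maxdim = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxdim), d(maxdim), z(maxdim + 1);
  std::vector<int> v(maxdim);

  // x axis
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)y * nx;
      f.assign(nx, 0.0);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, sp[0], d, v, z);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // y axis
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + x;
      f.assign(ny, 0.0);
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, sp[1], d, v, z);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // z axis
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      f.assign(nz, 0.0);
      for (int zz = 0; zz < nz; ++zz)
        f[zz] = out[base + (R_xlen_t)zz * nx * ny];
      dt1d(f, sp[2], d, v, z);
      for (int zz = 0; zz < nz; ++zz)
        out[base + (R_xlen_t)zz * nx * ny] = d[zz];
    }
  return out;
}

// 2D variant on a single slice (in-slice spacing only).
// [[Rcpp::export(name = ".edtSquared2d")]]
NumericVector edtSquared2d(LogicalVector mask, IntegerVector dm,
                           NumericVector sp) {
  const int nx = dm[0], ny = dm[1];
  const R_xlen_t n = (R_xlen_t)nx * ny;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;
  int maxdim = std::max(nx, ny);
  std::vector<double> f(maxdim), d(maxdim), z(maxdim + 1);
  std::vector<int> v(maxdim);
  for (int y = 0; y < ny; ++y) {
    R_xlen_t base = (R_xlen_t)y * nx;
    f.assign(nx, 0.0);
    for (int x = 0; x < nx; ++x) f[x] = out[base + x];
    dt1d(f, sp[0], d, v, z);
    for (int x = 0; x < nx; ++x) out[base + x] = d[x];
  }
  for (int x = 0; x < nx; ++x) {
    f.assign(ny, 0.0);
    for (int y = 0; y < ny; ++y) f[y] = out[x + (R_xlen_t)y * nx];
    dt1d(f, sp[1], d, v, z);
    for (int y = 0; y < ny; ++y) out[x + (R_xlen_t)y * nx] = d[y];
  }
  return out;
}

// 6-connected component of `mask` containing the (1-based) voxel `seed`.
// [[Rcpp::export(name = ".seedComponent")]]
LogicalVector seedComponent(LogicalVector mask, IntegerVector dm,
                            IntegerVector seed) {
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = FALSE;
  int sx = seed[0] - 1, sy = seed[1] - 1, sz = seed[2] - 1;
  R_xlen_t s0 = (R_xlen_t)sz * nx * ny + (R_xlen_t)sy * nx + sx;
  if (!mask[s0]) return out;
  std::vector<R_xlen_t> stack;
  stack.push_back(s0);
  out[s0] = TRUE;
  while (!stack.empty()) {
    R_xlen_t p = stack.back(); stack.pop_back();
    int x = (int)(p % nx);
    int y = (int)((p / nx) % ny);
    int zz = (int)(p / ((R_xlen_t)nx * ny));
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zc = zz + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zc < 0 || zc >= nz)
        continue;
      R_xlen_t q = (R_xlen_t)zc * nx * ny + (R_xlen_t)yy * nx + xx;
      if (mask[q] && !out[q]) { out[q] = TRUE; stack.push_back(q); }
    }
  }
  return out;
}
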