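#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
#include <queue>

using namespace Rcpp;

// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// sample positions i*step. Felzenszwalb & Huttenlocher style.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  double s2 = step * step;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
               (2.0 * s2 * (q - v[k]));
    while (k > 0 && s <= z[k]) {
      k--;
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = step * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel to the nearest TRUE voxel.
// Anisotropic spacing supported. Voxels inside the mask get distance 0.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? 0.0 : INF;

  // transform along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; x++) f[x] = g[base + x];
        dt1d(f, d, nx, spacing[0]);
        for (int x = 0; x < nx; x++) g[base + x] = d[x];
      }
  }
  // along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; z++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; y++) f[y] = g[base + (R_xlen_t)y * nx];
        dt1d(f, d, ny, spacing[1]);
        for (int y = 0; y < ny; y++) g[base + (R_xlen_t)y * nx] = d[y];
      }
  }
  // along z
  {
    std::vector<double> f(nz), d(nz);
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; z++) f[z] = g[base + (R_xlen_t)z * nx * ny];
        dt1d(f, d, nz, spacing[2]);
        for (int z = 0; z < nz; z++) g[base + (R_xlen_t)z * nx * ny] = d[z];
      }
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// 26-connected component labelling of a 3-D logical array.
// Labels are 1..k in first-encounter (column-major scan) order; background 0.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t c = q.front(); q.pop();
      int x = (int)(c % nx);
      int y = (int)((c / nx) % ny);
      int z = (int)(c / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t idx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (mask[idx] && !lab[idx]) { lab[idx] = next; q.push(idx); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
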