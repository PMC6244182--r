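#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher lower
// envelope) on a sampled grid with physical sample step `h`.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double h) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      double qq = (double)q * h, vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) k++;
    double vv = (double)v[k] * h;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Anisotropic 3D Euclidean distance transform: for every voxel, the
// distance (mm) to the nearest zero (background) voxel centre. Voxels in
// a grid with no zero voxel at all come back +Inf.
// [[Rcpp::export]]
NumericVector cpp_edt3d(NumericVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // large finite sentinel keeps the lower-envelope recursion stable;
  // voxels still at sentinel distance after all passes report +Inf
  const double BIG = 1e30;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = (mask[i] != 0.0) ? BIG : 0.0;

  std::vector<double> f, d;
  // axis 1 (rows, fastest)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f, d, spacing[0]);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }
  // axis 2 (columns)
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, spacing[1]);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // axis 3 (slices)
  f.resize(nz); d.resize(nz);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; z++) f[z] = out[base + (R_xlen_t)z * nxy];
      dt1d(f, d, spacing[2]);
      for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * nxy] = d[z];
    }
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (out[i] >= 1e29) ? R_PosInf : std::sqrt(out[i]);
  return out;
}

// Along-axis surface fill: for each 1-D ray along `axis` (1 = rows,
// 2 = columns, 3 = slices), mark every voxel between the start of the
// first and the end of the last run of >= minrun consecutive
// above-threshold voxels. Rays with no qualifying run stay background.
// [[Rcpp::export]]
LogicalVector cpp_ray_fill(NumericVector vol, IntegerVector dims,
                           double threshold, int axis, int minrun) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  LogicalVector out((R_xlen_t)nx * ny * nz);

  int len, n1, n2;
  if (axis == 1)      { len = nx; n1 = ny; n2 = nz; }
  else if (axis == 2) { len = ny; n1 = nx; n2 = nz; }
  else                { len = nz; n1 = nx; n2 = ny; }

  std::vector<R_xlen_t> idx(len);
  for (int b = 0; b < n2; b++)
    for (int a = 0; a < n1; a++) {
      for (int t = 0; t < len; t++) {
        if (axis == 1)      idx[t] = (R_xlen_t)b * nxy + (R_xlen_t)a * nx + t;
        else if (axis == 2) idx[t] = (R_xlen_t)b * nxy + (R_xlen_t)t * nx + a;
        else                idx[t] = (R_xlen_t)t * nxy + (R_xlen_t)b * nx + a;
      }
      int first = -1, last = -1, run = 0;
      for (int t = 0; t < len; t++) {
        if (vol[idx[t]] > threshold) {
          run++;
          if (run >= minrun) {
            if (first < 0) first = t - run + 1;
            last = t;
          }
        } else run = 0;
      }
      if (first >= 0)
        for (int t = first; t <= last; t++) out[idx[t]] = TRUE;
    }
  return out;
}

// 6-connectivity connected components of a binary 3D grid.
// Labels are assigned in scan order starting at 1; 0 is background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny, n = nxy * nz;
  IntegerVector lab(n);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t c = q.front(); q.pop();
      int z = (int)(c / nxy);
      int rem = (int)(c % nxy);
      int y = rem / nx, x = rem % nx;
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; k++) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t cc = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
        if (mask[cc] && lab[cc] == 0) { lab[cc] = next; q.push(cc); }
      }
    }
  }
  return lab;
}
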