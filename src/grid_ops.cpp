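#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Linear index helpers: R arrays are column-major, i fastest. All 0-based here.
static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// 26-connected region growing from a seed: BFS over voxels with values in
// [low, high]. Returns a logical mask.
// [[Rcpp::export(name = ".grow_region_cpp")]]
LogicalVector grow_region_cpp(NumericVector values, IntegerVector dims,
                              IntegerVector seed, double low, double high) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector mask(values.size(), false);
  std::queue<int> q;
  const int s = lin(seed[0], seed[1], seed[2], nx, ny);
  q.push(s);
  mask[s] = true;
  while (!q.empty()) {
    const int v = q.front(); q.pop();
    const int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          const int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          const int w = lin(ii, jj, kk, nx, ny);
          if (mask[w]) continue;
          const double x = values[w];
          if (ISNAN(x) || x < low || x > high) continue;
          mask[w] = true;
          q.push(w);
        }
  }
  return mask;
}

// 26-connected component labelling of a boolean mask. Labels are 1..K in
// order of first (lexicographically smallest) voxel encountered.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (int v = 0; v < mask.size(); ++v) {
    if (!mask[v] || lab[v] != 0) continue;
    ++next;
    lab[v] = next;
    q.push(v);
    while (!q.empty()) {
      const int u = q.front(); q.pop();
      const int i = u % nx, j = (u / nx) % ny, k = u / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            const int w = lin(ii, jj, kk, nx, ny);
            if (mask[w] && lab[w] == 0) { lab[w] = next; q.push(w); }
          }
    }
  }
  return lab;
}

// Face-connected (6-neighbour) boundary of a mask: mask voxels with at least
// one face neighbour outside the mask; the grid border counts as outside.
// [[Rcpp::export(name = ".mask_boundary_cpp")]]
LogicalVector mask_boundary_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(mask.size(), false);
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = lin(i, j, k, nx, ny);
        if (!mask[v]) continue;
        for (int n = 0; n < 6; ++n) {
          const int ii = i + d6[n][0], jj = j + d6[n][1], kk = k + d6[n][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz ||
              !mask[lin(ii, jj, kk, nx, ny)]) {
            out[v] = true;
            break;
          }
        }
      }
  return out;
}

// One face-connected erosion pass: keep mask voxels whose 6 face neighbours
// are all inside the mask (grid border counts as outside).
// [[Rcpp::export(name = ".erode_mask_cpp")]]
LogicalVector erode_mask_cpp(LogicalVector mask, IntegerVector dims) {
  LogicalVector b = mask_boundary_cpp(mask, dims);
  LogicalVector out(mask.size());
  for (int v = 0; v < mask.size(); ++v) out[v] = mask[v] && !b[v];
  return out;
}
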