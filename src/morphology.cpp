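#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Multi-source breadth/depth-first growth over a 3D in-band indicator.
// inband: logical vector of length nx*ny*nz, column-major (x fastest).
// seeds: 1-based linear indices, already validated in R.
// connectivity: 6 (face) or 26 (full).
// [[Rcpp::export]]
LogicalVector region_grow_cpp(const LogicalVector& inband, const IntegerVector& dim,
                              const IntegerVector& seeds, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    R_xlen_t idx = (R_xlen_t)seeds[s] - 1;
    if (inband[idx] && !out[idx]) { out[idx] = true; stack.push_back(idx); }
  }
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  while (!stack.empty()) {
    R_xlen_t idx = stack.back(); stack.pop_back();
    int x = (int)(idx % nx), y = (int)((idx / nx) % ny), z = (int)(idx / sz);
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (manh == 0) continue;
          if (connectivity == 6 && manh != 1) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          R_xlen_t nidx = idx + dx * sx + (R_xlen_t)dy * sy + (R_xlen_t)dz * sz;
          if (inband[nidx] && !out[nidx]) { out[nidx] = true; stack.push_back(nidx); }
        }
      }
    }
  }
  return out;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zbuf, int n) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -std::numeric_limits<double>::infinity();
  zbuf[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * (q - v[k]));
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// TRUE voxel of `mask`; separable 3-pass transform.
// [[Rcpp::export]]
NumericVector sedt_cpp(const LogicalVector& mask, const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;
  NumericVector dist(n);
  for (R_xlen_t i = 0; i < n; ++i) dist[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)y * nx + (R_xlen_t)z * sz;
      for (int x = 0; x < nx; ++x) f[x] = dist[base + x];
      dt1d(f, d, v, zbuf, nx);
      for (int x = 0; x < nx; ++x) dist[base + x] = d[x];
    }
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)x + (R_xlen_t)z * sz;
      for (int y = 0; y < ny; ++y) f[y] = dist[base + (R_xlen_t)y * nx];
      dt1d(f, d, v, zbuf, ny);
      for (int y = 0; y < ny; ++y) dist[base + (R_xlen_t)y * nx] = d[y];
    }
  // along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)x + (R_xlen_t)y * nx;
      for (int z = 0; z < nz; ++z) f[z] = dist[base + (R_xlen_t)z * sz];
      dt1d(f, d, v, zbuf, nz);
      for (int z = 0; z < nz; ++z) dist[base + (R_xlen_t)z * sz] = d[z];
    }
  return dist;
}

// r iterations of dilation by the face-connected unit element
// (equivalently: city-block distance to the mask <= r).
// [[Rcpp::export]]
LogicalVector dilate_face_cpp(const LogicalVector& mask, const IntegerVector& dim, int iter) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  LogicalVector out(n);
  std::vector<R_xlen_t> frontier, next;
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = mask[i];
    if (mask[i]) frontier.push_back(i);
  }
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  for (int it = 0; it < iter && !frontier.empty(); ++it) {
    next.clear();
    for (R_xlen_t fi = 0; fi < (R_xlen_t)frontier.size(); ++fi) {
      R_xlen_t idx = frontier[fi];
      int x = (int)(idx % nx), y = (int)((idx / nx) % ny), z = (int)(idx / sz);
      for (int k = 0; k < 6; ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t nidx = (R_xlen_t)xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * sz;
        if (!out[nidx]) { out[nidx] = true; next.push_back(nidx); }
      }
    }
    frontier.swap(next);
  }
  return out;
}
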