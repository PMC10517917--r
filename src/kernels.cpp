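#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Index helpers: volumes are passed as flat vectors with dim = (nx, ny, nz),
// column-major as in R arrays.
static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// reflect index into [0, n)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dim, int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (radius <= 0) return clone(vol);
  NumericVector out(vol.size());
  const int w = 2 * radius + 1;
  std::vector<double> win;
  win.reserve((size_t)w * w * w);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        win.clear();
        for (int dk = -radius; dk <= radius; ++dk) {
          int kk = reflect(k + dk, nz);
          for (int dj = -radius; dj <= radius; ++dj) {
            int jj = reflect(j + dj, ny);
            for (int di = -radius; di <= radius; ++di) {
              int ii = reflect(i + di, nx);
              win.push_back(vol[idx3(ii, jj, kk, nx, ny)]);
            }
          }
        }
        size_t mid = win.size() / 2;
        std::nth_element(win.begin(), win.begin() + mid, win.end());
        out[idx3(i, j, k, nx, ny)] = win[mid];
      }
    }
  }
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) applied in
// place along a strided line.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  const double INF = 1e20;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from each TRUE voxel to the nearest FALSE voxel
// (voxel-center to voxel-center). FALSE voxels get 0. A volume with no FALSE
// voxel returns a large sentinel distance.
// [[Rcpp::export]]
NumericVector cpp_edt3d_sq(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = 1e20;
  NumericVector g(mask.size());
  for (R_xlen_t t = 0; t < mask.size(); ++t) g[t] = mask[t] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) g[idx3(i, j, k, nx, ny)] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j) g[idx3(i, j, k, nx, ny)] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k) g[idx3(i, j, k, nx, ny)] = d[k];
    }
  return g;
}

// Connected-component labeling of TRUE voxels, 6- or 26-connectivity.
// Labels are 1..K in discovery order; background 0.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<int> stack;
  int next = 0;
  // neighbor offsets
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1)
          continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int nn = (int)di.size();
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int k = cur / (nx * ny);
      int rem = cur % (nx * ny);
      int j = rem / nx;
      int i = rem % nx;
      for (int t = 0; t < nn; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int q = idx3(ii, jj, kk, nx, ny);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Per-z-slice 2D hole filling: returns mask with any FALSE region not
// 4-connected to the slice border set to TRUE.
// [[Rcpp::export]]
LogicalVector cpp_fill_slices(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size());
  std::vector<char> reach((size_t)nx * ny);
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    const int off = nx * ny * k;
    for (int i = 0; i < nx; ++i) {
      for (int jb : {0, ny - 1}) {
        int q = i + nx * jb;
        if (!mask[off + q] && !reach[q]) { reach[q] = 1; stack.push_back(q); }
      }
    }
    for (int j = 0; j < ny; ++j) {
      for (int ib : {0, nx - 1}) {
        int q = ib + nx * j;
        if (!mask[off + q] && !reach[q]) { reach[q] = 1; stack.push_back(q); }
      }
    }
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int j = cur / nx, i = cur % nx;
      const int nbi[4] = {i - 1, i + 1, i, i};
      const int nbj[4] = {j, j, j - 1, j + 1};
      for (int t = 0; t < 4; ++t) {
        if (nbi[t] < 0 || nbi[t] >= nx || nbj[t] < 0 || nbj[t] >= ny) continue;
        int q = nbi[t] + nx * nbj[t];
        if (!mask[off + q] && !reach[q]) { reach[q] = 1; stack.push_back(q); }
      }
    }
    for (int q = 0; q < nx * ny; ++q)
      out[off + q] = mask[off + q] || !reach[q];
  }
  return out;
}

static inline double bilinear(const NumericMatrix& img, double x, double y) {
  const int nx = img.nrow(), ny = img.ncol();
  int ix = (int)std::floor(x), iy = (int)std::floor(y);
  double fx = x - ix, fy = y - iy;
  double v = 0.0;
  for (int a = 0; a <= 1; ++a)
    for (int b = 0; b <= 1; ++b) {
      int xi = ix + a, yi = iy + b;
      if (xi < 0 || xi >= nx || yi < 0 || yi >= ny) continue;
      double w = (a ? fx : 1.0 - fx) * (b ? fy : 1.0 - fy);
      v += w * img(xi, yi);
    }
  return v;
}

// Parallel-beam projection of one slice. Rays are sampled at unit (voxel)
// steps with bilinear interpolation; line integrals are in units of
// attenuation x voxel length. Returns n_angles x dw.
// [[Rcpp::export]]
NumericMatrix cpp_radon_slice(NumericMatrix img, NumericVector angles_rad,
                              int dw) {
  const int na = angles_rad.size();
  const double cx = (img.nrow() - 1) / 2.0, cy = (img.ncol() - 1) / 2.0;
  const double s0 = (dw - 1) / 2.0;
  NumericMatrix out(na, dw);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int is = 0; is < dw; ++is) {
      const double s = is - s0;
      double acc = 0.0;
      for (int it = 0; it < dw; ++it) {
        const double t = it - s0;
        const double x = cx + s * ct - t * st;
        const double y = cy + s * st + t * ct;
        if (x < -1 || x > img.nrow() || y < -1 || y > img.ncol()) continue;
        acc += bilinear(img, x, y);
      }
      out(a, is) = acc;
    }
  }
  return out;
}

// Back-projection of filtered projections (n_angles x dw) onto an nx x ny
// grid, with linear interpolation along the detector. The caller applies the
// pi / (2 n_angles) normalization.
// [[Rcpp::export]]
NumericMatrix cpp_backproject_slice(NumericMatrix fsino,
                                    NumericVector angles_rad,
                                    int nx, int ny) {
  const int na = angles_rad.size(), dw = fsino.ncol();
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double s0 = (dw - 1) / 2.0;
  NumericMatrix out(nx, ny);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles_rad[a]), st = std::sin(angles_rad[a]);
    for (int j = 0; j < ny; ++j) {
      const double yr = j - cy;
      for (int i = 0; i < nx; ++i) {
        const double s = (i - cx) * ct + yr * st + s0;
        int is = (int)std::floor(s);
        double fs = s - is;
        double v = 0.0;
        if (is >= 0 && is < dw) v += (1.0 - fs) * fsino(a, is);
        if (is + 1 >= 0 && is + 1 < dw) v += fs * fsino(a, is + 1);
        out(i, j) += v;
      }
    }
  }
  return out;
}
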