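#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Low-level 3D grid kernels shared by the segmentation and nucleus modules.
// Volumes are R arrays indexed [x, y, z] (column-major); `dim` is c(nx,ny,nz).

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// Separable 1D convolution along one axis (1=x, 2=y, 3=z), reflect padding.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int k = kernel.size(), r = (k - 1) / 2;
  NumericVector out(vol.size());
  const int n = (axis == 1) ? nx : (axis == 2) ? ny : nz;
  std::vector<double> line(n), res(n);

  const int n_outer = (axis == 1) ? ny * nz : (axis == 2) ? nx * nz : nx * ny;
  for (int o = 0; o < n_outer; ++o) {
    // decode the fixed coordinates of this line
    int a, b;
    R_xlen_t base;
    R_xlen_t stride;
    if (axis == 1) {
      a = o % ny; b = o / ny;               // y, z
      base = idx3(0, a, b, nx, ny); stride = 1;
    } else if (axis == 2) {
      a = o % nx; b = o / nx;               // x, z
      base = idx3(a, 0, b, nx, ny); stride = nx;
    } else {
      a = o % nx; b = o / nx;               // x, y
      base = idx3(a, b, 0, nx, ny); stride = (R_xlen_t)nx * ny;
    }
    for (int i = 0; i < n; ++i) line[i] = vol[base + stride * i];
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        int p = i + j - r;
        if (p < 0) p = -p - 1;              // reflect
        if (p >= n) p = 2 * n - p - 1;
        if (p < 0) p = 0;                   // very short lines
        if (p >= n) p = n - 1;
        s += line[p] * kernel[j];
      }
      res[i] = s;
    }
    for (int i = 0; i < n; ++i) out[base + stride * i] = res[i];
  }
  return out;
}

// Felzenszwalb & Huttenlocher 1D squared distance transform with sample
// spacing w (positions x_i = i*w).
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n, double w,
                 std::vector<int> &v, std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int kk = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * w;
    while (true) {
      if (f[v[kk]] == INF) { // empty parabola so far
        if (kk == 0) { v[0] = q; z[0] = -INF; z[1] = INF; break; }
        --kk; continue;
      }
      double xv = v[kk] * w;
      double s = ((f[q] + xq * xq) - (f[v[kk]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[kk]) { --kk; continue; }
      ++kk; v[kk] = q; z[kk] = s; z[kk + 1] = INF;
      break;
    }
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    double xq = q * w;
    while (z[kk + 1] < xq) ++kk;
    double xv = v[kk] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[kk]];
  }
}

// Squared anisotropic Euclidean distance (um^2) from every voxel to the
// nearest TRUE voxel. All-FALSE input returns Inf everywhere.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector D(feature.size());
  for (R_xlen_t i = 0; i < feature.size(); ++i)
    D[i] = feature[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int axis = 1; axis <= 3; ++axis) {
    const int n = (axis == 1) ? nx : (axis == 2) ? ny : nz;
    const double w = spacing[axis - 1];
    const int n_outer = (axis == 1) ? ny * nz : (axis == 2) ? nx * nz : nx * ny;
    for (int o = 0; o < n_outer; ++o) {
      int a, b; R_xlen_t base, stride;
      if (axis == 1) {
        a = o % ny; b = o / ny; base = idx3(0, a, b, nx, ny); stride = 1;
      } else if (axis == 2) {
        a = o % nx; b = o / nx; base = idx3(a, 0, b, nx, ny); stride = nx;
      } else {
        a = o % nx; b = o / nx; base = idx3(a, b, 0, nx, ny);
        stride = (R_xlen_t)nx * ny;
      }
      bool any_finite = false;
      for (int i = 0; i < n; ++i) {
        f[i] = D[base + stride * i];
        if (f[i] < INF) any_finite = true;
      }
      if (!any_finite) continue;
      dt1d(f, d, n, w, v, z);
      for (int i = 0; i < n; ++i) D[base + stride * i] = d[i];
    }
  }
  return D;
}

// 6-connectivity connected-component labeling; labels 1..K, background 0.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        R_xlen_t i0 = idx3(x0, y0, z0, nx, ny);
        if (!mask[i0] || lab[i0]) continue;
        ++next;
        lab[i0] = next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          R_xlen_t i = stack.back(); stack.pop_back();
          int x = (int)(i % nx), y = (int)((i / nx) % ny), zz = (int)(i / ((R_xlen_t)nx * ny));
          for (int q = 0; q < 6; ++q) {
            int xn = x + dx[q], yn = y + dy[q], zn = zz + dz[q];
            if (xn < 0 || yn < 0 || zn < 0 || xn >= nx || yn >= ny || zn >= nz)
              continue;
            R_xlen_t j = idx3(xn, yn, zn, nx, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  return lab;
}

// 1-based linear indices of 26-neighborhood local maxima strictly above
// `threshold`. Plateau ties are broken toward the smallest linear index.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_local_maxima(NumericVector vol, IntegerVector dim,
                               double threshold) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> hits;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        double v = vol[i];
        if (!(v > threshold)) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1 && ismax; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xn = x + dx, yn = y + dy, zn = z + dz;
              if (xn < 0 || yn < 0 || zn < 0 || xn >= nx || yn >= ny || zn >= nz)
                continue;
              R_xlen_t j = idx3(xn, yn, zn, nx, ny);
              if (vol[j] > v || (vol[j] == v && j < i)) ismax = false;
            }
        if (ismax) hits.push_back((int)(i + 1));
      }
  return wrap(hits);
}

// Sequential hard-sphere acceptance: keep candidate rows (um coordinates)
// whose distance to every previously accepted point is >= min_dist. Stops
// after n_target acceptances. Returns 1-based indices of accepted rows.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_hardsphere_accept(NumericMatrix cand, NumericMatrix existing,
                                    double min_dist, int n_target) {
  const double d2min = min_dist * min_dist;
  // cell list with cell edge = min_dist
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = std::numeric_limits<double>::infinity();
    hi[a] = -lo[a];
  }
  auto upd = [&](double x, int a) {
    if (x < lo[a]) lo[a] = x;
    if (x > hi[a]) hi[a] = x;
  };
  for (int i = 0; i < cand.nrow(); ++i)
    for (int a = 0; a < 3; ++a) upd(cand(i, a), a);
  for (int i = 0; i < existing.nrow(); ++i)
    for (int a = 0; a < 3; ++a) upd(existing(i, a), a);
  if (!std::isfinite(lo[0])) return IntegerVector(0);

  const double cell = std::max(min_dist, 1e-9);
  int ncell[3];
  for (int a = 0; a < 3; ++a)
    ncell[a] = std::max(1, (int)std::floor((hi[a] - lo[a]) / cell) + 1);
  std::vector<std::vector<int>> bins((size_t)ncell[0] * ncell[1] * ncell[2]);
  std::vector<double> px, py, pz;
  auto cell_of = [&](double x, double y, double z) {
    int cx = std::min(ncell[0] - 1, std::max(0, (int)((x - lo[0]) / cell)));
    int cy = std::min(ncell[1] - 1, std::max(0, (int)((y - lo[1]) / cell)));
    int cz = std::min(ncell[2] - 1, std::max(0, (int)((z - lo[2]) / cell)));
    return (size_t)cx + (size_t)ncell[0] * ((size_t)cy + (size_t)ncell[1] * cz);
  };
  auto add_pt = [&](double x, double y, double z) {
    px.push_back(x); py.push_back(y); pz.push_back(z);
    bins[cell_of(x, y, z)].push_back((int)px.size() - 1);
  };
  auto clash = [&](double x, double y, double z) {
    int cx = (int)((x - lo[0]) / cell), cy = (int)((y - lo[1]) / cell),
        cz = (int)((z - lo[2]) / cell);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int ax = cx + dx, ay = cy + dy, az = cz + dz;
          if (ax < 0 || ay < 0 || az < 0 || ax >= ncell[0] || ay >= ncell[1] ||
              az >= ncell[2])
            continue;
          const std::vector<int> &b =
              bins[(size_t)ax + (size_t)ncell[0] * ((size_t)ay + (size_t)ncell[1] * az)];
          for (int j : b) {
            double ddx = x - px[j], ddy = y - py[j], ddz = z - pz[j];
            if (ddx * ddx + ddy * ddy + ddz * ddz < d2min) return true;
          }
        }
    return false;
  };
  for (int i = 0; i < existing.nrow(); ++i)
    add_pt(existing(i, 0), existing(i, 1), existing(i, 2));

  std::vector<int> accepted;
  for (int i = 0; i < cand.nrow() && (int)accepted.size() < n_target; ++i) {
    double x = cand(i, 0), y = cand(i, 1), z = cand(i, 2);
    if (clash(x, y, z)) continue;
    add_pt(x, y, z);
    accepted.push_back(i + 1);
  }
  return wrap(accepted);
}
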