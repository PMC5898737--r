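// Low-level 3D image primitives: resampling, separable Gaussian smoothing,
// affine resampling, morphological dilation, connected-component labelling.
// All arrays are R column-major 3D arrays indexed [x, y, z].
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Cell-centered (align-corners-false) trilinear or nearest-neighbour resize.
// Output voxel i maps to input coordinate (i + 0.5) * n_in / n_out - 0.5,
// clamped at the edges so constants are preserved exactly.
// [[Rcpp::export]]
NumericVector cpp_resize3d(NumericVector x, IntegerVector in_dim,
                           IntegerVector out_dim, bool nearest) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  const int mx = out_dim[0], my = out_dim[1], mz = out_dim[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double sx = (double)nx / mx, sy = (double)ny / my, sz = (double)nz / mz;
  const double* X = x.begin();
  double* O = out.begin();
  for (int k = 0; k < mz; ++k) {
    double gz = (k + 0.5) * sz - 0.5;
    for (int j = 0; j < my; ++j) {
      double gy = (j + 0.5) * sy - 0.5;
      for (int i = 0; i < mx; ++i) {
        double gx = (i + 0.5) * sx - 0.5;
        double v;
        if (nearest) {
          int ix = clampi((int)std::lround(gx), 0, nx - 1);
          int iy = clampi((int)std::lround(gy), 0, ny - 1);
          int iz = clampi((int)std::lround(gz), 0, nz - 1);
          v = X[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        } else {
          int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy), z0 = (int)std::floor(gz);
          double fx = gx - x0, fy = gy - y0, fz = gz - z0;
          int x0c = clampi(x0, 0, nx - 1), x1c = clampi(x0 + 1, 0, nx - 1);
          int y0c = clampi(y0, 0, ny - 1), y1c = clampi(y0 + 1, 0, ny - 1);
          int z0c = clampi(z0, 0, nz - 1), z1c = clampi(z0 + 1, 0, nz - 1);
          double v000 = X[x0c + (R_xlen_t)nx * (y0c + (R_xlen_t)ny * z0c)];
          double v100 = X[x1c + (R_xlen_t)nx * (y0c + (R_xlen_t)ny * z0c)];
          double v010 = X[x0c + (R_xlen_t)nx * (y1c + (R_xlen_t)ny * z0c)];
          double v110 = X[x1c + (R_xlen_t)nx * (y1c + (R_xlen_t)ny * z0c)];
          double v001 = X[x0c + (R_xlen_t)nx * (y0c + (R_xlen_t)ny * z1c)];
          double v101 = X[x1c + (R_xlen_t)nx * (y0c + (R_xlen_t)ny * z1c)];
          double v011 = X[x0c + (R_xlen_t)nx * (y1c + (R_xlen_t)ny * z1c)];
          double v111 = X[x1c + (R_xlen_t)nx * (y1c + (R_xlen_t)ny * z1c)];
          double c00 = v000 * (1 - fx) + v100 * fx;
          double c10 = v010 * (1 - fx) + v110 * fx;
          double c01 = v001 * (1 - fx) + v101 * fx;
          double c11 = v011 * (1 - fx) + v111 * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          v = c0 * (1 - fz) + c1 * fz;
        }
        O[i + (R_xlen_t)mx * (j + (R_xlen_t)my * k)] = v;
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing with reflecting boundaries.
// sigma is given in voxels per axis; kernel truncated at 3.5 sigma.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector x, IntegerVector dim,
                                  NumericVector sigma_vox) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t nvox = (R_xlen_t)n[0] * n[1] * n[2];
  NumericVector buf(clone(x));
  NumericVector tmp(nvox);
  const R_xlen_t stride[3] = {1, (R_xlen_t)n[0], (R_xlen_t)n[0] * n[1]};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.5 * s);
    std::vector<double> ker(2 * rad + 1);
    double tot = 0;
    for (int t = -rad; t <= rad; ++t) {
      ker[t + rad] = std::exp(-0.5 * t * t / (s * s));
      tot += ker[t + rad];
    }
    for (double& k : ker) k /= tot;
    const int len = n[ax];
    const R_xlen_t st = stride[ax];
    double* B = buf.begin();
    double* T = tmp.begin();
    std::vector<double> line(len + 2 * rad);
    // iterate over all lines along axis ax
    int oa = (ax == 0) ? 1 : 0, ob = (ax == 2) ? 1 : 2;
    for (int b = 0; b < n[ob]; ++b) {
      for (int a = 0; a < n[oa]; ++a) {
        R_xlen_t base = (R_xlen_t)a * stride[oa] + (R_xlen_t)b * stride[ob];
        // gather the line with reflected (mirror) padding
        for (int i = 0; i < len; ++i) line[rad + i] = B[base + (R_xlen_t)i * st];
        for (int t = 1; t <= rad; ++t) {
          int ql = t - 1, qr = len - t;  // reflect without repeating the edge
          line[rad - t] = B[base + (R_xlen_t)std::min(ql, len - 1) * st];
          line[rad + len - 1 + t] = B[base + (R_xlen_t)std::max(qr, 0) * st];
        }
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          const double* lp = &line[i];
          for (int t = 0; t <= 2 * rad; ++t) acc += ker[t] * lp[t];
          T[base + (R_xlen_t)i * st] = acc;
        }
      }
    }
    std::copy(tmp.begin(), tmp.end(), buf.begin());
  }
  return buf;
}

// Affine resampling. A is a 3x4 matrix mapping *output* 0-based voxel
// indices (homogeneous) to input voxel coordinates. Out-of-field samples
// take `fill`.
// [[Rcpp::export]]
NumericVector cpp_affine_resample3d(NumericVector x, IntegerVector dim,
                                    NumericMatrix A, bool nearest, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* X = x.begin();
  double* O = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double gx = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + A(0, 3);
        double gy = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + A(1, 3);
        double gz = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + A(2, 3);
        double v = fill;
        if (nearest) {
          int ix = (int)std::lround(gx), iy = (int)std::lround(gy), iz = (int)std::lround(gz);
          if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz)
            v = X[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        } else {
          int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy), z0 = (int)std::floor(gz);
          if (x0 >= -1 && x0 < nx && y0 >= -1 && y0 < ny && z0 >= -1 && z0 < nz) {
            double fx = gx - x0, fy = gy - y0, fz = gz - z0;
            double acc = 0;
            for (int dz = 0; dz <= 1; ++dz)
              for (int dy = 0; dy <= 1; ++dy)
                for (int dx = 0; dx <= 1; ++dx) {
                  int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
                  double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                  double s = (xi >= 0 && xi < nx && yi >= 0 && yi < ny && zi >= 0 && zi < nz)
                                 ? X[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)]
                                 : fill;
                  acc += w * s;
                }
            v = acc;
          }
        }
        O[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = v;
      }
  return out;
}

// Dilation of a binary mask by a Euclidean ball of radius_mm given voxel
// spacing (mm). Offsets are precomputed; complexity O(|mask| * |ball|).
// [[Rcpp::export]]
IntegerVector cpp_ball_dilate(IntegerVector m, IntegerVector dim,
                              NumericVector spacing, double radius_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out(clone(m));
  if (radius_mm <= 0) return out;
  int rx = (int)std::floor(radius_mm / spacing[0]);
  int ry = (int)std::floor(radius_mm / spacing[1]);
  int rz = (int)std::floor(radius_mm / spacing[2]);
  std::vector<int> offs;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double d2 = dx * spacing[0] * dx * spacing[0] + dy * spacing[1] * dy * spacing[1] +
                    dz * spacing[2] * dz * spacing[2];
        if (d2 <= radius_mm * radius_mm) {
          offs.push_back(dx);
          offs.push_back(dy);
          offs.push_back(dz);
        }
      }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!m[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)]) continue;
        for (size_t o = 0; o < offs.size(); o += 3) {
          int xi = x + offs[o], yi = y + offs[o + 1], zi = z + offs[o + 2];
          if (xi >= 0 && xi < nx && yi >= 0 && yi < ny && zi >= 0 && zi < nz)
            out[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)] = 1;
        }
      }
  return out;
}

// One iteration of binary dilation with the full 3x3x3 cube (26-connectivity
// neighbourhood including the centre).
// [[Rcpp::export]]
IntegerVector cpp_cube_dilate(IntegerVector m, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!m[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)]) continue;
        int z0 = std::max(z - 1, 0), z1 = std::min(z + 1, nz - 1);
        int y0 = std::max(y - 1, 0), y1 = std::min(y + 1, ny - 1);
        int x0 = std::max(x - 1, 0), x1 = std::min(x + 1, nx - 1);
        for (int zi = z0; zi <= z1; ++zi)
          for (int yi = y0; yi <= y1; ++yi)
            for (int xi = x0; xi <= x1; ++xi)
              out[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)] = 1;
      }
  return out;
}

// 26-connectivity connected-component labelling (BFS flood fill).
// Returns an integer array: 0 background, components numbered from 1.
// [[Rcpp::export]]
IntegerVector cpp_label26(IntegerVector m, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(nvox);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!m[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front();
      q.pop();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xi = x + dx, yi = y + dy, zi = z + dz;
            if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz) continue;
            R_xlen_t u = xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi);
            if (m[u] && !lab[u]) {
              lab[u] = next;
              q.push(u);
            }
          }
    }
  }
  return lab;
}
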