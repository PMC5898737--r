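// Volumetric CNN primitives for the 3-level U-Net: same-padded 3x3x3 (or
// 1x1x1) convolution, 2x2x2 max-pooling with stride 2, and 2x
// nearest-neighbour upsampling, each with its backward pass.
//
// Convolutions are computed directly (no im2col): the working set per
// output row is a handful of input rows, so the computation stays in
// cache and memory traffic is one read of the input plus one write of
// the output per layer.
//
// Feature maps are R arrays of dim (nx, ny, nz, channels), column-major.
// A convolution's weights are a (k^3 * c_in) x c_out matrix whose rows are
// ordered channel-major: row = ci * k^3 + o, where o enumerates the kernel
// offsets (dx fastest, then dy, then dz).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dim,
                             NumericMatrix W, NumericVector b, int k) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], cin = dim[3];
  const int cout = W.ncol();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox * cout);
  const double* X = x.begin();
  const double* Wp = W.begin();
  const int wrows = W.nrow();
  double* O = out.begin();
  std::vector<double> acc(nx);
  if (k == 1) {
    for (int co = 0; co < cout; ++co) {
      double* oc = O + co * nvox;
      std::fill(oc, oc + nvox, b[co]);
      for (int ci = 0; ci < cin; ++ci) {
        const double w = Wp[ci + (R_xlen_t)co * wrows];
        const double* xc = X + ci * nvox;
        for (R_xlen_t v = 0; v < nvox; ++v) oc[v] += w * xc[v];
      }
    }
    out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
    return out;
  }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int co = 0; co < cout; ++co) {
        std::fill(acc.begin(), acc.end(), b[co]);
        const double* wc = Wp + (R_xlen_t)co * wrows;
        for (int ci = 0; ci < cin; ++ci) {
          const double* xc = X + ci * nvox;
          const double* wci = wc + ci * 27;
          for (int dz = -1; dz <= 1; ++dz) {
            const int sz = z + dz;
            if (sz < 0 || sz >= nz) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              const int sy = y + dy;
              if (sy < 0 || sy >= ny) continue;
              const double* row = xc + (R_xlen_t)nx * (sy + (R_xlen_t)ny * sz);
              const double* w3 = wci + (dz + 1) * 9 + (dy + 1) * 3;
              const double w0 = w3[0], w1 = w3[1], w2 = w3[2];
              // dx = -1, 0, +1 fused over the contiguous x run
              acc[0] += w1 * row[0] + w2 * row[1];
              for (int xx = 1; xx < nx - 1; ++xx)
                acc[xx] += w0 * row[xx - 1] + w1 * row[xx] + w2 * row[xx + 1];
              acc[nx - 1] += w0 * row[nx - 2] + w1 * row[nx - 1];
            }
          }
        }
        double* orow = O + co * nvox + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        std::copy(acc.begin(), acc.end(), orow);
      }
    }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dim, NumericMatrix W,
                    NumericVector dout, int k) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], cin = dim[3];
  const int cout = W.ncol();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double* X = x.begin();
  const double* dO = dout.begin();
  const double* Wp = W.begin();
  const int wrows = W.nrow();
  NumericVector dx(nvox * cin);
  NumericMatrix dW(W.nrow(), W.ncol());
  NumericVector db(cout);
  double* dXp = dx.begin();
  double* dWp = dW.begin();
  for (int co = 0; co < cout; ++co) {
    const double* dc = dO + co * nvox;
    double s = 0;
    for (R_xlen_t v = 0; v < nvox; ++v) s += dc[v];
    db[co] = s;
  }
  if (k == 1) {
    for (int ci = 0; ci < cin; ++ci) {
      const double* xc = X + ci * nvox;
      double* dxc = dXp + ci * nvox;
      for (int co = 0; co < cout; ++co) {
        const double w = Wp[ci + (R_xlen_t)co * wrows];
        const double* dc = dO + co * nvox;
        double g = 0;
        for (R_xlen_t v = 0; v < nvox; ++v) {
          dxc[v] += w * dc[v];
          g += xc[v] * dc[v];
        }
        dWp[ci + (R_xlen_t)co * wrows] = g;
      }
    }
    dx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
    return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
  }
  // dX: correlation of dOut with the flipped kernel;
  // dW: per-offset dot products of shifted input rows with dOut rows.
  std::vector<double> acc(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int ci = 0; ci < cin; ++ci) {
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int co = 0; co < cout; ++co) {
          const double* dc = dO + co * nvox;
          const double* wci = Wp + (R_xlen_t)co * wrows + ci * 27;
          for (int dz = -1; dz <= 1; ++dz) {
            const int sz = z - dz;  // dX[u] += W[o] * dOut[u - d_o]
            if (sz < 0 || sz >= nz) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              const int sy = y - dy;
              if (sy < 0 || sy >= ny) continue;
              const double* row = dc + (R_xlen_t)nx * (sy + (R_xlen_t)ny * sz);
              const double* w3 = wci + (dz + 1) * 9 + (dy + 1) * 3;
              const double w0 = w3[0], w1 = w3[1], w2 = w3[2];
              // dx offsets mirrored: dX[x] += w(dx) * dOut[x - dx]
              acc[0] += w1 * row[0] + w0 * row[1];
              for (int xx = 1; xx < nx - 1; ++xx)
                acc[xx] += w2 * row[xx - 1] + w1 * row[xx] + w0 * row[xx + 1];
              acc[nx - 1] += w2 * row[nx - 2] + w1 * row[nx - 1];
            }
          }
        }
        double* drow = dXp + ci * nvox + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        std::copy(acc.begin(), acc.end(), drow);
      }
      // dW accumulation for this output row
      for (int co = 0; co < cout; ++co) {
        const double* drow = dO + co * nvox + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int ci = 0; ci < cin; ++ci) {
          const double* xc = X + ci * nvox;
          double* dwci = dWp + (R_xlen_t)co * wrows + ci * 27;
          for (int dz = -1; dz <= 1; ++dz) {
            const int sz = z + dz;
            if (sz < 0 || sz >= nz) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              const int sy = y + dy;
              if (sy < 0 || sy >= ny) continue;
              const double* xrow = xc + (R_xlen_t)nx * (sy + (R_xlen_t)ny * sz);
              double* w3 = dwci + (dz + 1) * 9 + (dy + 1) * 3;
              double g0 = 0, g1 = 0, g2 = 0;
              // dW[o] += sum_x X[x + dx] * dOut[x]
              for (int xx = 1; xx < nx - 1; ++xx) {
                const double d = drow[xx];
                g0 += xrow[xx - 1] * d;
                g1 += xrow[xx] * d;
                g2 += xrow[xx + 1] * d;
              }
              g1 += xrow[0] * drow[0] + xrow[nx - 1] * drow[nx - 1];
              g2 += xrow[1] * drow[0];
              g0 += xrow[nx - 2] * drow[nx - 1];
              w3[0] += g0;
              w3[1] += g1;
              w3[2] += g2;
            }
          }
        }
      }
    }
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2x2 max pooling with stride 2; ties resolved to the first voxel in
// (x, y, z) scan order. Returns pooled map and 1-based argmax indices.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], ch = dim[3];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const R_xlen_t nin = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nout = (R_xlen_t)mx * my * mz;
  NumericVector out(nout * ch);
  IntegerVector arg(nout * ch);
  for (int c = 0; c < ch; ++c) {
    const double* X = x.begin() + c * nin;
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y)
        for (int xo = 0; xo < mx; ++xo) {
          double best = -INFINITY;
          R_xlen_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                R_xlen_t idx = (2 * xo + dx) +
                               (R_xlen_t)nx * ((2 * y + dy) + (R_xlen_t)ny * (2 * z + dz));
                if (X[idx] > best) {
                  best = X[idx];
                  bi = idx;
                }
              }
          R_xlen_t o = xo + (R_xlen_t)mx * (y + (R_xlen_t)my * z) + c * nout;
          out[o] = best;
          arg[o] = (int)(bi + c * nin) + 1;
        }
  }
  out.attr("dim") = IntegerVector::create(mx, my, mz, ch);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector argmax,
                              IntegerVector in_dim) {
  NumericVector dx((R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i] - 1] += dout[i];
  dx.attr("dim") = in_dim;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], ch = dim[3];
  const int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  const R_xlen_t nin = (R_xlen_t)nx * ny * nz, nout = (R_xlen_t)mx * my * mz;
  NumericVector out(nout * ch);
  for (int c = 0; c < ch; ++c)
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y) {
        const double* src = x.begin() + c * nin +
                            (R_xlen_t)nx * ((y / 2) + (R_xlen_t)ny * (z / 2));
        double* dst = out.begin() + c * nout + (R_xlen_t)mx * (y + (R_xlen_t)my * z);
        for (int xo = 0; xo < mx; ++xo) dst[xo] = src[xo / 2];
      }
  out.attr("dim") = IntegerVector::create(mx, my, mz, ch);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dout, IntegerVector in_dim) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], ch = in_dim[3];
  const int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  const R_xlen_t nin = (R_xlen_t)nx * ny * nz, nout = (R_xlen_t)mx * my * mz;
  NumericVector dx(nin * ch);
  for (int c = 0; c < ch; ++c)
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y) {
        const double* src = dout.begin() + c * nout + (R_xlen_t)mx * (y + (R_xlen_t)my * z);
        double* dst = dx.begin() + c * nin +
                      (R_xlen_t)nx * ((y / 2) + (R_xlen_t)ny * (z / 2));
        for (int xo = 0; xo < mx; ++xo) dst[xo / 2] += src[xo];
      }
  dx.attr("dim") = in_dim;
  return dx;
}
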