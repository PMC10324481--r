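// Low-level kernels for the 3D convolutional U-net: im2col/col2im with
// circular or zero same-padding, 2x max pooling and nearest upsampling.
// Activations are laid out as R arrays dim c(nx, ny, nz, C). The im2col
// matrix is built transposed — n_voxels rows by (k^3 * Cin) columns, column
// index dx-fastest then dy, dz, channel — so that each column is filled with
// contiguous x-runs and convolution is `cols %*% matrix(W, k^3*Cin, Cout)`,
// producing the (nx, ny, nz, Cout) output directly in array order.
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int wrap(int i, int n) {
  i %= n;
  return i < 0 ? i + n : i;
}

// copy one x-row (fixed sy, sz, channel) into a column of the cols matrix,
// shifted by ox with circular wrap or zero padding
static void copy_row(double* dst, const double* src, int nx, int ox,
                     bool circular) {
  if (circular) {
    for (int ix = 0; ix < nx; ++ix) dst[ix] = src[wrap(ix + ox, nx)];
  } else {
    for (int ix = 0; ix < nx; ++ix) {
      int sx = ix + ox;
      dst[ix] = (sx >= 0 && sx < nx) ? src[sx] : 0.0;
    }
  }
}

static void add_row(double* dst, const double* src, int nx, int ox,
                    bool circular) {
  if (circular) {
    for (int ix = 0; ix < nx; ++ix) dst[wrap(ix + ox, nx)] += src[ix];
  } else {
    for (int ix = 0; ix < nx; ++ix) {
      int sx = ix + ox;
      if (sx >= 0 && sx < nx) dst[sx] += src[ix];
    }
  }
}

// [[Rcpp::export]]
arma::mat pn_im2col(const arma::vec& x, int nx, int ny, int nz, int cin,
                    int k, bool circular) {
  const int pad = (k - 1) / 2;
  const int nvox = nx * ny * nz;
  arma::mat cols(nvox, k * k * k * cin, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x.memptr() + (size_t)ci * nvox;
    for (int dz = 0; dz < k; ++dz) {
      const int oz = dz - pad;
      for (int dy = 0; dy < k; ++dy) {
        const int oy = dy - pad;
        for (int dx = 0; dx < k; ++dx) {
          const int ox = dx - pad;
          // column order must match matrix(W, k^3*cin): dx fastest
          double* cp = cols.colptr(ci * k * k * k +
                                   k * (dy + k * dz) + dx);
          for (int iz = 0; iz < nz; ++iz) {
            int sz = iz + oz;
            if (circular) sz = wrap(sz, nz);
            else if (sz < 0 || sz >= nz) continue;
            for (int iy = 0; iy < ny; ++iy) {
              int sy = iy + oy;
              if (circular) sy = wrap(sy, ny);
              else if (sy < 0 || sy >= ny) continue;
              copy_row(cp + nx * (iy + (size_t)ny * iz),
                       xc + nx * (sy + (size_t)ny * sz), nx, ox, circular);
            }
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of pn_im2col: scatter column gradients back onto the input grid
// [[Rcpp::export]]
arma::vec pn_col2im(const arma::mat& cols, int nx, int ny, int nz, int cin,
                    int k, bool circular) {
  const int pad = (k - 1) / 2;
  const int nvox = nx * ny * nz;
  arma::vec x((size_t)nvox * cin, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    double* xc = x.memptr() + (size_t)ci * nvox;
    for (int dz = 0; dz < k; ++dz) {
      const int oz = dz - pad;
      for (int dy = 0; dy < k; ++dy) {
        const int oy = dy - pad;
        for (int dx = 0; dx < k; ++dx) {
          const int ox = dx - pad;
          const double* cp = cols.colptr(ci * k * k * k +
                                         k * (dy + k * dz) + dx);
          for (int iz = 0; iz < nz; ++iz) {
            int sz = iz + oz;
            if (circular) sz = wrap(sz, nz);
            else if (sz < 0 || sz >= nz) continue;
            for (int iy = 0; iy < ny; ++iy) {
              int sy = iy + oy;
              if (circular) sy = wrap(sy, ny);
              else if (sy < 0 || sy >= ny) continue;
              add_row(xc + nx * (sy + (size_t)ny * sz),
                      cp + nx * (iy + (size_t)ny * iz), nx, ox, circular);
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2x2 max pooling, stride 2; returns pooled values and 1-based argmax
// indices into the input for the backward pass
// [[Rcpp::export]]
List pn_maxpool(const arma::vec& x, int nx, int ny, int nz, int c) {
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int nvox = nx * ny * nz, ovox = ox * oy * oz;
  arma::vec out((size_t)ovox * c);
  IntegerVector arg((size_t)ovox * c);
  for (int ci = 0; ci < c; ++ci) {
    const double* xc = x.memptr() + (size_t)ci * nvox;
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix) {
          double best = -arma::datum::inf;
          int besti = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int idx = (2 * ix + dx) + nx * ((2 * iy + dy) +
                          ny * (2 * iz + dz));
                if (xc[idx] > best) { best = xc[idx]; besti = idx; }
              }
          size_t o = (size_t)ci * ovox + ix + ox * (iy + oy * iz);
          out(o) = best;
          arg[o] = besti + 1 + ci * nvox;
        }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
arma::vec pn_maxpool_bwd(const arma::vec& dout, const IntegerVector& argmax,
                         int n_in) {
  arma::vec dx(n_in, arma::fill::zeros);
  for (int i = 0; i < (int)dout.n_elem; ++i) dx(argmax[i] - 1) += dout(i);
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
arma::vec pn_upsample(const arma::vec& x, int nx, int ny, int nz, int c) {
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const int nvox = nx * ny * nz, ovox = ox * oy * oz;
  arma::vec out((size_t)ovox * c);
  for (int ci = 0; ci < c; ++ci) {
    const double* xc = x.memptr() + (size_t)ci * nvox;
    double* oc = out.memptr() + (size_t)ci * ovox;
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix)
          oc[ix + ox * (iy + oy * iz)] =
            xc[(ix / 2) + nx * ((iy / 2) + ny * (iz / 2))];
  }
  return out;
}

// [[Rcpp::export]]
arma::vec pn_upsample_bwd(const arma::vec& dout, int nx, int ny, int nz,
                          int c) {
  // nx, ny, nz are the *input* (coarse) dims
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const int nvox = nx * ny * nz, ovox = ox * oy * oz;
  arma::vec dx((size_t)nvox * c, arma::fill::zeros);
  for (int ci = 0; ci < c; ++ci) {
    const double* dc = dout.memptr() + (size_t)ci * ovox;
    double* xc = dx.memptr() + (size_t)ci * nvox;
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix)
          xc[(ix / 2) + nx * ((iy / 2) + ny * (iz / 2))] +=
            dc[ix + ox * (iy + oy * iz)];
  }
  return dx;
}
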