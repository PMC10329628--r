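#include <Rcpp.h>
using namespace Rcpp;

// 3D convolution primitives for feature maps stored as R arrays of
// dim (C, X, Y, Z) (channel fastest, column-major).  3x3x3 kernels with
// zero padding 1 are expressed as im2col + BLAS matmul on the R side.

// Batched: the input stacks B samples along z, each of extent Z; kernel
// neighbourhoods never cross sample boundaries (they see zero padding).
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector x, int C, int X, int Y, int Z, int B) {
  const int nvox = X*Y*Z*B;
  NumericMatrix out(27*C, nvox);
  const double *px = REAL(x);
  double *po = REAL(out);
  for (int b = 0; b < B; ++b)
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx) {
        const int v = xx + X*(y + Y*(z + Z*b));
        double *col = po + (size_t)v * 27 * C;
        for (int o = 0; o < 27; ++o) {
          const int ox = o % 3 - 1, oy = (o/3) % 3 - 1, oz = o/9 - 1;
          const int sx = xx+ox, sy = y+oy, sz = z+oz;
          if (sx < 0 || sx >= X || sy < 0 || sy >= Y || sz < 0 || sz >= Z) {
            for (int c = 0; c < C; ++c) col[c + C*o] = 0.0;
          } else {
            const double *src = px + (size_t)C * (sx + X*(sy + Y*(sz + Z*b)));
            for (int c = 0; c < C; ++c) col[c + C*o] = src[c];
          }
        }
      }
  return out;
}

// Adjoint of cpp_im2col3: scatter-add column gradients back to the input.
// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericMatrix cols, int C, int X, int Y, int Z, int B) {
  NumericVector out((size_t)C*X*Y*Z*B);
  const double *pc = REAL(cols);
  double *po = REAL(out);
  for (int b = 0; b < B; ++b)
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx) {
        const int v = xx + X*(y + Y*(z + Z*b));
        const double *col = pc + (size_t)v * 27 * C;
        for (int o = 0; o < 27; ++o) {
          const int ox = o % 3 - 1, oy = (o/3) % 3 - 1, oz = o/9 - 1;
          const int sx = xx+ox, sy = y+oy, sz = z+oz;
          if (sx < 0 || sx >= X || sy < 0 || sy >= Y || sz < 0 || sz >= Z) continue;
          double *dst = po + (size_t)C * (sx + X*(sy + Y*(sz + Z*b)));
          for (int c = 0; c < C; ++c) dst[c] += col[c + C*o];
        }
      }
  return out;
}

// 2x max pooling (dims must be even); returns pooled values and 0-based
// argmax linear indices into the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool3(NumericVector x, int C, int X, int Y, int Z) {
  const int Xo = X/2, Yo = Y/2, Zo = Z/2;
  NumericVector out((size_t)C*Xo*Yo*Zo);
  IntegerVector arg((size_t)C*Xo*Yo*Zo);
  const double *px = REAL(x);
  for (int z = 0; z < Zo; ++z)
    for (int y = 0; y < Yo; ++y)
      for (int xx = 0; xx < Xo; ++xx)
        for (int c = 0; c < C; ++c) {
          double best = -R_PosInf; int bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const size_t i = c + (size_t)C*((2*xx+dx) + X*((2*y+dy) + Y*(2*z+dz)));
                if (px[i] > best) { best = px[i]; bi = (int)i; }
              }
          const size_t o = c + (size_t)C*(xx + Xo*(y + Yo*z));
          out[o] = best; arg[o] = bi;
        }
  return List::create(_["y"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxunpool3(NumericVector gy, IntegerVector arg, int n_in) {
  NumericVector out(n_in);
  for (R_xlen_t i = 0; i < gy.size(); ++i) out[arg[i]] += gy[i];
  return out;
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export]]
NumericVector cpp_upsample3(NumericVector x, int C, int X, int Y, int Z) {
  const int Xo = 2*X, Yo = 2*Y, Zo = 2*Z;
  NumericVector out((size_t)C*Xo*Yo*Zo);
  const double *px = REAL(x);
  double *po = REAL(out);
  for (int z = 0; z < Zo; ++z)
    for (int y = 0; y < Yo; ++y)
      for (int xx = 0; xx < Xo; ++xx) {
        const double *src = px + (size_t)C*((xx/2) + X*((y/2) + Y*(z/2)));
        double *dst = po + (size_t)C*(xx + Xo*(y + Yo*z));
        for (int c = 0; c < C; ++c) dst[c] = src[c];
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3_adj(NumericVector gy, int C, int X, int Y, int Z) {
  // X, Y, Z are the *coarse* dims; gy has dims (C, 2X, 2Y, 2Z)
  const int Xo = 2*X, Yo = 2*Y, Zo = 2*Z;
  NumericVector out((size_t)C*X*Y*Z);
  const double *pg = REAL(gy);
  double *po = REAL(out);
  for (int z = 0; z < Zo; ++z)
    for (int y = 0; y < Yo; ++y)
      for (int xx = 0; xx < Xo; ++xx) {
        const double *src = pg + (size_t)C*(xx + Xo*(y + Yo*z));
        double *dst = po + (size_t)C*((xx/2) + X*((y/2) + Y*(z/2)));
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  return out;
}


// Per-sample channel means over stacked batches: z is (C x V*B); returns
// (C x B) means over each sample's V voxels.
// [[Rcpp::export]]
NumericMatrix cpp_block_rowmeans(NumericMatrix z, int V, int B) {
  const int C = z.nrow();
  NumericMatrix out(C, B);
  const double *pz = REAL(z);
  double *po = REAL(out);
  for (int b = 0; b < B; ++b) {
    for (int v = 0; v < V; ++v) {
      const double *col = pz + (size_t)C * (v + (size_t)V*b);
      for (int c = 0; c < C; ++c) po[c + C*b] += col[c];
    }
    for (int c = 0; c < C; ++c) po[c + C*b] /= V;
  }
  return out;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif
// Return freed heap pages to the OS; long simulation loops with varying
// sparse-factor sizes otherwise grow resident memory by fragmentation.
// [[Rcpp::export]]
void cpp_malloc_trim() {
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}
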