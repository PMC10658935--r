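// Patch-gathering kernels for the U-Net convolutions.
//
// Tensors are column-major R arrays laid out (H, W, N, C) for the 2D arm
// (N = batch of slices) and (H, W, D, C) for the 3D arm (D = slices of one
// volume). im2col gathers k x k (x k) zero-padded neighbourhoods into a
// (H*W*N) x (k*k*C) matrix so convolution becomes one BLAS matmul;
// col2im scatter-adds the gradient back.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col2d_cpp(NumericVector x, int H, int W, int N, int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericMatrix P(no_init(rows, (R_xlen_t)k * k * C));
  const double* xp = x.begin();
  double* Pp = P.begin();
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      const int block = dj * k + di;
      for (int c = 0; c < C; ++c) {
        double* out = Pp + ((R_xlen_t)block * C + c) * rows;
        const double* src = xp + (R_xlen_t)c * H * W * N;
        for (int n = 0; n < N; ++n) {
          const double* vol = src + (R_xlen_t)n * H * W;
          double* o = out + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dj - p;
            double* oc = o + (R_xlen_t)w * H;
            if (ws < 0 || ws >= W) {
              for (int h = 0; h < H; ++h) oc[h] = 0.0;
              continue;
            }
            const double* sc = vol + (R_xlen_t)ws * H;
            const int lo = std::max(0, p - di);
            const int hi = std::min(H, H + p - di);
            for (int h = 0; h < lo; ++h) oc[h] = 0.0;
            for (int h = lo; h < hi; ++h) oc[h] = sc[h + di - p];
            for (int h = hi; h < H; ++h) oc[h] = 0.0;
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector col2im2d_cpp(NumericMatrix dP, int H, int W, int N, int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericVector dx((R_xlen_t)H * W * N * C);
  const double* Pp = dP.begin();
  double* xp = dx.begin();
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      const int block = dj * k + di;
      for (int c = 0; c < C; ++c) {
        const double* in = Pp + ((R_xlen_t)block * C + c) * rows;
        double* dst = xp + (R_xlen_t)c * H * W * N;
        for (int n = 0; n < N; ++n) {
          const double* i0 = in + (R_xlen_t)n * H * W;
          double* vol = dst + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dj - p;
            if (ws < 0 || ws >= W) continue;
            const double* ic = i0 + (R_xlen_t)w * H;
            double* dc = vol + (R_xlen_t)ws * H;
            const int lo = std::max(0, p - di);
            const int hi = std::min(H, H + p - di);
            for (int h = lo; h < hi; ++h) dc[h + di - p] += ic[h];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}

// [[Rcpp::export]]
NumericMatrix im2col3d_cpp(NumericVector x, int H, int W, int D, int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * D;
  NumericMatrix P(no_init(rows, (R_xlen_t)k * k * k * C));
  const double* xp = x.begin();
  double* Pp = P.begin();
  for (int dk = 0; dk < k; ++dk) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int block = (dk * k + dj) * k + di;
        for (int c = 0; c < C; ++c) {
          double* out = Pp + ((R_xlen_t)block * C + c) * rows;
          const double* src = xp + (R_xlen_t)c * H * W * D;
          for (int d = 0; d < D; ++d) {
            const int ds = d + dk - p;
            double* o = out + (R_xlen_t)d * H * W;
            if (ds < 0 || ds >= D) {
              for (R_xlen_t i = 0; i < (R_xlen_t)H * W; ++i) o[i] = 0.0;
              continue;
            }
            const double* vol = src + (R_xlen_t)ds * H * W;
            for (int w = 0; w < W; ++w) {
              const int ws = w + dj - p;
              double* oc = o + (R_xlen_t)w * H;
              if (ws < 0 || ws >= W) {
                for (int h = 0; h < H; ++h) oc[h] = 0.0;
                continue;
              }
              const double* sc = vol + (R_xlen_t)ws * H;
              const int lo = std::max(0, p - di);
              const int hi = std::min(H, H + p - di);
              for (int h = 0; h < lo; ++h) oc[h] = 0.0;
              for (int h = lo; h < hi; ++h) oc[h] = sc[h + di - p];
              for (int h = hi; h < H; ++h) oc[h] = 0.0;
            }
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector col2im3d_cpp(NumericMatrix dP, int H, int W, int D, int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * D;
  NumericVector dx((R_xlen_t)H * W * D * C);
  const double* Pp = dP.begin();
  double* xp = dx.begin();
  for (int dk = 0; dk < k; ++dk) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int block = (dk * k + dj) * k + di;
        for (int c = 0; c < C; ++c) {
          const double* in = Pp + ((R_xlen_t)block * C + c) * rows;
          double* dst = xp + (R_xlen_t)c * H * W * D;
          for (int d = 0; d < D; ++d) {
            const int ds = d + dk - p;
            if (ds < 0 || ds >= D) continue;
            const double* i0 = in + (R_xlen_t)d * H * W;
            double* vol = dst + (R_xlen_t)ds * H * W;
            for (int w = 0; w < W; ++w) {
              const int ws = w + dj - p;
              if (ws < 0 || ws >= W) continue;
              const double* ic = i0 + (R_xlen_t)w * H;
              double* dc = vol + (R_xlen_t)ws * H;
              const int lo = std::max(0, p - di);
              const int hi = std::min(H, H + p - di);
              for (int h = lo; h < hi; ++h) dc[h + di - p] += ic[h];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, D, C);
  return dx;
}
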