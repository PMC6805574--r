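#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Internal tensor layout throughout the package: (H, W, N, C), column-major.
// Weight matrices for convolutions: (k*k*Cin) x Cout with row index
// r = ki + k*kj + k*k*c  (ki = kernel row, kj = kernel col, c = input channel).
// im2col column index: col = oh + oH*(ow + oW*n).

static inline int conv_out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int oH = conv_out_dim(H, k, stride, pad);
  const int oW = conv_out_dim(W, k, stride, pad);
  if (oH < 1 || oW < 1) stop("convolution output would be empty");
  NumericMatrix P(k * k * C, oH * oW * N);
  const double *px = x.begin();
  double *pp = P.begin();
  const int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const R_xlen_t col = (R_xlen_t)oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * n);
        double *dst = pp + col * nrow;
        const int h0 = oh * stride - pad;
        const int w0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double *src = px + ((R_xlen_t)c * N + n) * H * W;
          for (int kj = 0; kj < k; ++kj) {
            const int w = w0 + kj;
            for (int ki = 0; ki < k; ++ki) {
              const int h = h0 + ki;
              double v = 0.0;
              if (h >= 0 && h < H && w >= 0 && w < W)
                v = src[h + (R_xlen_t)H * w];
              dst[ki + k * kj + k * k * c] = v;
            }
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix P, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int oH = conv_out_dim(H, k, stride, pad);
  const int oW = conv_out_dim(W, k, stride, pad);
  NumericVector x((R_xlen_t)H * W * N * C);
  double *px = x.begin();
  const double *pp = P.begin();
  const int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const R_xlen_t col = (R_xlen_t)oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * n);
        const double *src = pp + col * nrow;
        const int h0 = oh * stride - pad;
        const int w0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          double *dst = px + ((R_xlen_t)c * N + n) * H * W;
          for (int kj = 0; kj < k; ++kj) {
            const int w = w0 + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h = h0 + ki;
              if (h < 0 || h >= H) continue;
              dst[h + (R_xlen_t)H * w] += src[ki + k * kj + k * k * c];
            }
          }
        }
      }
    }
  }
  return x;
}

static inline int pool_out_dim(int in, int k, int stride, int pad, bool ceil_mode) {
  int o;
  if (ceil_mode) {
    o = (int)std::ceil((double)(in + 2 * pad - k) / stride) + 1;
    // do not start a window beyond the (padded) input
    if ((o - 1) * stride >= in + pad) --o;
  } else {
    o = (in + 2 * pad - k) / stride + 1;
  }
  return o;
}

// Max pooling; windows are clipped to the valid input region (implicit -Inf
// padding).  Returns the pooled tensor with an "argmax" attribute holding
// 1-based linear indices into x, used by the backward pass.
// [[Rcpp::export]]
List maxpool_fw_cpp(NumericVector x, int H, int W, int N, int C,
                    int k, int stride, int pad, bool ceil_mode) {
  const int oH = pool_out_dim(H, k, stride, pad, ceil_mode);
  const int oW = pool_out_dim(W, k, stride, pad, ceil_mode);
  if (oH < 1 || oW < 1) stop("pooling output would be empty");
  NumericVector out((R_xlen_t)oH * oW * N * C);
  IntegerVector arg((R_xlen_t)oH * oW * N * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const R_xlen_t xoff = ((R_xlen_t)c * N + n) * H * W;
      const R_xlen_t ooff = ((R_xlen_t)c * N + n) * oH * oW;
      for (int ow = 0; ow < oW; ++ow) {
        int w0 = ow * stride - pad, w1 = w0 + k;
        if (w0 < 0) w0 = 0;
        if (w1 > W) w1 = W;
        for (int oh = 0; oh < oH; ++oh) {
          int h0 = oh * stride - pad, h1 = h0 + k;
          if (h0 < 0) h0 = 0;
          if (h1 > H) h1 = H;
          double best = -DBL_MAX;
          R_xlen_t bidx = xoff + h0 + (R_xlen_t)H * w0;
          for (int w = w0; w < w1; ++w) {
            for (int h = h0; h < h1; ++h) {
              const double v = px[xoff + h + (R_xlen_t)H * w];
              if (v > best) { best = v; bidx = xoff + h + (R_xlen_t)H * w; }
            }
          }
          out[ooff + oh + (R_xlen_t)oH * ow] = best;
          arg[ooff + oh + (R_xlen_t)oH * ow] = (int)(bidx + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg,
                      _["oH"] = oH, _["oW"] = oW);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(NumericVector dout, IntegerVector argmax,
                             R_xlen_t input_len) {
  NumericVector dx(input_len);
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    dx[argmax[i] - 1] += dout[i];
  return dx;
}
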