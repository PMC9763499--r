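#include <Rcpp.h>
using namespace Rcpp;

// Activations are stored as C x (H*W*N) matrices: row = channel, column
// index = h + H*(w-1) + H*W*(n-1) (height fastest). im2col unrolls K_h x K_w
// patches so convolution becomes one dgemm against a C_out x (C*KH*KW)
// weight matrix; row order of the patch matrix is channel fastest, then
// kernel height, then kernel width.

// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col_cpp(const NumericMatrix& x, int H, int W, int N,
                         int KH, int KW, int SH, int SW, int PH, int PW) {
  const int C = x.nrow();
  const int OH = (H + 2 * PH - KH) / SH + 1;
  const int OW = (W + 2 * PW - KW) / SW + 1;
  NumericMatrix out(C * KH * KW, OH * OW * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const int outRows = C * KH * KW;
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)C * H * W * n;
    for (int ow = 0; ow < OW; ++ow) {
      const int w0 = ow * SW - PW;
      for (int oh = 0; oh < OH; ++oh) {
        const int h0 = oh * SH - PH;
        double* col = op + (size_t)outRows * (oh + OH * (ow + (size_t)OW * n));
        for (int kw = 0; kw < KW; ++kw) {
          const int w = w0 + kw;
          for (int kh = 0; kh < KH; ++kh) {
            const int h = h0 + kh;
            double* dst = col + (size_t)C * (kh + KH * kw);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              const double* src = xn + (size_t)C * (h + (size_t)H * w);
              std::copy(src, src + C, dst);
            } else {
              std::fill(dst, dst + C, 0.0);
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-adds patch-matrix gradients back onto the
// (C x H*W*N) input layout. Overlapping patches accumulate.

// [[Rcpp::export(name = ".col2im")]]
NumericMatrix col2im_cpp(const NumericMatrix& cols, int C, int H, int W,
                         int N, int KH, int KW, int SH, int SW,
                         int PH, int PW) {
  const int OH = (H + 2 * PH - KH) / SH + 1;
  const int OW = (W + 2 * PW - KW) / SW + 1;
  NumericMatrix out(C, H * W * N);
  const double* cp = cols.begin();
  double* op = out.begin();
  const int colRows = C * KH * KW;
  for (int n = 0; n < N; ++n) {
    double* xn = op + (size_t)C * H * W * n;
    for (int ow = 0; ow < OW; ++ow) {
      const int w0 = ow * SW - PW;
      for (int oh = 0; oh < OH; ++oh) {
        const int h0 = oh * SH - PH;
        const double* col =
            cp + (size_t)colRows * (oh + OH * (ow + (size_t)OW * n));
        for (int kw = 0; kw < KW; ++kw) {
          const int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < KH; ++kh) {
            const int h = h0 + kh;
            if (h < 0 || h >= H) continue;
            const double* src = col + (size_t)C * (kh + KH * kw);
            double* dst = xn + (size_t)C * (h + (size_t)H * w);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return out;
}
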