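#include <Rcpp.h>
using namespace Rcpp;

// Feature tensors are stored as dense matrices with rows enumerating
// (row h fastest, then column w, then sample n) and one column per channel.
// row index = h + H*w + H*W*n   (0-based)
//
// im2col lays out receptive fields so that a convolution becomes a single
// GEMM against a (filters x k*k*C) weight matrix:
//   patch row index = kh + k*kw + k*k*c
//   patch col index = oh + oH*ow + oH*oW*n

// [[Rcpp::export(rng = false)]]
NumericMatrix im2col_nchw(NumericMatrix x, int H, int W, int N,
                          int k, int stride, int pad) {
  const int C = x.ncol();
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix cols(k * k * C, oH * oW * N);
  const double* xp = x.begin();
  double* cp = cols.begin();
  const int nrow_cols = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      const int w0 = ow * stride - pad;
      for (int oh = 0; oh < oH; ++oh) {
        const int h0 = oh * stride - pad;
        double* col = cp + (std::size_t)nrow_cols *
          (oh + (std::size_t)oH * ow + (std::size_t)oH * oW * n);
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + (std::size_t)x.nrow() * c +
            (std::size_t)H * W * n;
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            double* dst = col + k * kw + k * k * c;
            if (w < 0 || w >= W) {
              for (int kh = 0; kh < k; ++kh) dst[kh] = 0.0;
            } else {
              const double* src = xc + (std::size_t)H * w;
              for (int kh = 0; kh < k; ++kh) {
                const int h = h0 + kh;
                dst[kh] = (h < 0 || h >= H) ? 0.0 : src[h];
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export(rng = false)]]
NumericMatrix col2im_nchw(NumericMatrix cols, int H, int W, int N, int C,
                          int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix x((std::size_t)H * W * N, C);
  const double* cp = cols.begin();
  double* xp = x.begin();
  const int nrow_cols = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      const int w0 = ow * stride - pad;
      for (int oh = 0; oh < oH; ++oh) {
        const int h0 = oh * stride - pad;
        const double* col = cp + (std::size_t)nrow_cols *
          (oh + (std::size_t)oH * ow + (std::size_t)oH * oW * n);
        for (int c = 0; c < C; ++c) {
          double* xc = xp + (std::size_t)x.nrow() * c + (std::size_t)H * W * n;
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            const double* src = col + k * kw + k * k * c;
            double* dst = xc + (std::size_t)H * w;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h >= 0 && h < H) dst[h] += src[kh];
            }
          }
        }
      }
    }
  }
  return x;
}

// Max pooling (no padding).  Returns the pooled matrix and, for each pooled
// value, the 1-based row index of the winning input element (first maximum
// wins on ties, scanning kw-major then kh) so the backward pass can
// scatter gradients.  Separable implementation: a vertical max pass over
// rows, then a horizontal pass over the vertical maxima; the combined
// tie-break (smallest kw, then smallest kh) equals the direct window scan.
// [[Rcpp::export(rng = false)]]
List maxpool_fwd(NumericMatrix x, int H, int W, int N, int k, int stride) {
  const int C = x.ncol();
  const int oH = (H - k) / stride + 1;
  const int oW = (W - k) / stride + 1;
  NumericMatrix out((std::size_t)oH * oW * N, C);
  IntegerMatrix idx((std::size_t)oH * oW * N, C);
  const double* xp = x.begin();
  std::vector<double> vm((std::size_t)oH * W);
  std::vector<int> vi((std::size_t)oH * W);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (std::size_t)x.nrow() * c;
    for (int n = 0; n < N; ++n) {
      const std::size_t in_off = (std::size_t)H * W * n;
      // vertical pass: max over each k-tall window, every column
      for (int w = 0; w < W; ++w) {
        const double* col = xc + in_off + (std::size_t)H * w;
        double* vmc = vm.data() + (std::size_t)oH * w;
        int* vic = vi.data() + (std::size_t)oH * w;
        for (int r = 0; r < oH; ++r) {
          const int h0 = r * stride;
          double best = col[h0];
          int bi = h0;
          for (int kh = 1; kh < k; ++kh) {
            if (col[h0 + kh] > best) { best = col[h0 + kh]; bi = h0 + kh; }
          }
          vmc[r] = best; vic[r] = bi;
        }
      }
      // horizontal pass over the vertical maxima
      for (int ow = 0; ow < oW; ++ow) {
        const int w0 = ow * stride;
        const std::size_t o0 = (std::size_t)oH * ow +
          (std::size_t)oH * oW * n;
        for (int r = 0; r < oH; ++r) {
          double best = vm[(std::size_t)oH * w0 + r];
          int bw = w0;
          for (int kw = 1; kw < k; ++kw) {
            const double v = vm[(std::size_t)oH * (w0 + kw) + r];
            if (v > best) { best = v; bw = w0 + kw; }
          }
          out(o0 + r, c) = best;
          idx(o0 + r, c) = (int)(in_off + (std::size_t)H * bw +
                                 vi[(std::size_t)oH * bw + r]) + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(rng = false)]]
NumericMatrix maxpool_bwd(NumericMatrix dout, IntegerMatrix idx,
                          int in_rows) {
  const int C = dout.ncol();
  NumericMatrix dx(in_rows, C);
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < dout.nrow(); ++i) {
      dx(idx(i, c) - 1, c) += dout(i, c);
    }
  }
  return dx;
}
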