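#include <Rcpp.h>
using namespace Rcpp;

// Image tensors are [H, W, C] numeric arrays in R's column-major layout:
// element (h, w, c) sits at h + H*w + H*W*c (0-based).
//
// im2col lowers a convolution to a GEMM: each output position (ho, wo)
// becomes one column holding the k x k x C input patch it sees. Patch rows
// are ordered (ki, kj, c) with ki fastest; columns ordered (ho, wo) with
// ho fastest, so the GEMM result reshapes straight into an [Ho, Wo, Cout]
// array. Zero padding of `pad` pixels on all sides, stride `stride`.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, Ho * Wo);
  const double* xp = x.begin();
  double* op = out.begin();
  const int nrow = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* col = op + (size_t)(wo * Ho + ho) * nrow;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (size_t)c * H * W;
        for (int kj = 0; kj < k; ++kj) {
          const int w = w0 + kj;
          const bool wok = (w >= 0 && w < W);
          for (int ki = 0; ki < k; ++ki) {
            const int h = h0 + ki;
            double v = 0.0;
            if (wok && h >= 0 && h < H) v = xc[(size_t)w * H + h];
            col[c * k * k + kj * k + ki] = v;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add patch-gradient columns back onto the
// input grid. `cols` must have the layout produced by cpp_im2col.

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((size_t)H * W * C);
  double* xp = x.begin();
  const double* cp = cols.begin();
  const int nrow = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* col = cp + (size_t)(wo * Ho + ho) * nrow;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = xp + (size_t)c * H * W;
        for (int kj = 0; kj < k; ++kj) {
          const int w = w0 + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int h = h0 + ki;
            if (h < 0 || h >= H) continue;
            xc[(size_t)w * H + h] += col[c * k * k + kj * k + ki];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Box-window mean with windows clipped at the image borders (each output
// pixel averages over the part of the (2r+1)^2 window that lies inside the
// image). Used by the DOPU kernel average.

// [[Rcpp::export]]
NumericMatrix cpp_box_mean_clipped(NumericMatrix x, int r) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  // integral image with a zero top row / left column
  std::vector<double> S((size_t)(H + 1) * (W + 1), 0.0);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      S[(size_t)(w + 1) * (H + 1) + (h + 1)] =
          x(h, w) + S[(size_t)w * (H + 1) + (h + 1)] +
          S[(size_t)(w + 1) * (H + 1) + h] - S[(size_t)w * (H + 1) + h];
  for (int w = 0; w < W; ++w) {
    const int w0 = std::max(0, w - r), w1 = std::min(W - 1, w + r);
    for (int h = 0; h < H; ++h) {
      const int h0 = std::max(0, h - r), h1 = std::min(H - 1, h + r);
      const double sum = S[(size_t)(w1 + 1) * (H + 1) + (h1 + 1)] -
                         S[(size_t)w0 * (H + 1) + (h1 + 1)] -
                         S[(size_t)(w1 + 1) * (H + 1) + h0] +
                         S[(size_t)w0 * (H + 1) + h0];
      out(h, w) = sum / ((double)(h1 - h0 + 1) * (w1 - w0 + 1));
    }
  }
  return out;
}
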