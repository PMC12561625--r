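// Low-level kernels for the autodiff engine: im2col / col2im (lowering 2-d
// convolution to BLAS matmul) and direct depthwise convolution.
// Array layout follows R: column-major, dims (H, W, C), element (i, j, c)
// at linear index i + H*j + H*W*c.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const int N = Hout * Wout;
  NumericMatrix out(N, k * k * C);
  const double* xp = x.begin();
  double* op0 = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = (c * k + dj) * k + di;
        double* op = op0 + (R_xlen_t)col * N;
        for (int oj = 0; oj < Wout; ++oj) {
          const int j = oj * stride + dj - pad;
          const bool jin = (j >= 0 && j < W);
          for (int oi = 0; oi < Hout; ++oi) {
            const int i = oi * stride + di - pad;
            double v = 0.0;
            if (jin && i >= 0 && i < H) v = xp[i + (R_xlen_t)H * j + (R_xlen_t)H * W * c];
            op[oi + (R_xlen_t)Hout * oj] = v;
          }
        }
      }
    }
  }
  return out;
}

// adjoint of cpp_im2col: scatter-add patch columns back into the image
// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const int N = Hout * Wout;
  NumericVector x((R_xlen_t)H * W * C);
  double* xp = x.begin();
  const double* cp0 = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = (c * k + dj) * k + di;
        const double* cp = cp0 + (R_xlen_t)col * N;
        for (int oj = 0; oj < Wout; ++oj) {
          const int j = oj * stride + dj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Hout; ++oi) {
            const int i = oi * stride + di - pad;
            if (i < 0 || i >= H) continue;
            xp[i + (R_xlen_t)H * j + (R_xlen_t)H * W * c] += cp[oi + (R_xlen_t)Hout * oj];
          }
        }
      }
    }
  }
  return x;
}

// depthwise k x k convolution, stride 1, zero pad (k-1)/2 ("same")
// w: k*k x C matrix (kernel for channel c in column c, di fastest then dj)
// [[Rcpp::export]]
NumericVector cpp_dwconv(const NumericVector& x, int H, int W, int C,
                         const NumericMatrix& w, int k) {
  const int pad = (k - 1) / 2;
  NumericVector out((R_xlen_t)H * W * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)H * W * c;
    double* oc = op + (R_xlen_t)H * W * c;
    const double* wc = &w(0, c);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double acc = 0.0;
        for (int dj = 0; dj < k; ++dj) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int ii = i + di - pad;
            if (ii < 0 || ii >= H) continue;
            acc += wc[dj * k + di] * xc[ii + (R_xlen_t)H * jj];
          }
        }
        oc[i + (R_xlen_t)H * j] = acc;
      }
    }
  }
  return out;
}

// gradient of cpp_dwconv w.r.t. its input: correlation with the flipped
// kernel, which equals dwconv with kernel index reversed
// [[Rcpp::export]]
NumericVector cpp_dwconv_dx(const NumericVector& g, int H, int W, int C,
                            const NumericMatrix& w, int k) {
  const int pad = (k - 1) / 2;
  NumericVector out((R_xlen_t)H * W * C);
  const double* gp = g.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = gp + (R_xlen_t)H * W * c;
    double* oc = op + (R_xlen_t)H * W * c;
    const double* wc = &w(0, c);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double acc = 0.0;
        for (int dj = 0; dj < k; ++dj) {
          const int jj = j - (dj - pad);
          if (jj < 0 || jj >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int ii = i - (di - pad);
            if (ii < 0 || ii >= H) continue;
            acc += wc[dj * k + di] * gc[ii + (R_xlen_t)H * jj];
          }
        }
        oc[i + (R_xlen_t)H * j] = acc;
      }
    }
  }
  return out;
}

// gradient of cpp_dwconv w.r.t. the kernel
// [[Rcpp::export]]
NumericMatrix cpp_dwconv_dw(const NumericVector& x, const NumericVector& g,
                            int H, int W, int C, int k) {
  const int pad = (k - 1) / 2;
  NumericMatrix dw(k * k, C);
  const double* xp = x.begin();
  const double* gp = g.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)H * W * c;
    const double* gc = gp + (R_xlen_t)H * W * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        double acc = 0.0;
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di - pad;
            if (ii < 0 || ii >= H) continue;
            acc += gc[i + (R_xlen_t)H * j] * xc[ii + (R_xlen_t)H * jj];
          }
        }
        dw(dj * k + di, c) = acc;
      }
    }
  }
  return dw;
}
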