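#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as a C x (H*W*N) matrix: each column is one pixel,
// columns ordered column-major within an image (row index fastest), images
// consecutive. im2col rows are ordered patch-position fastest within channel:
// row = c*k^2 + (kw*k + kh).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, int H, int W, int N,
                         int k, int stride, int pad) {
  const int C = X.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int k2 = k * k;
  NumericMatrix out(C * k2, Ho * Wo * N);
  const double* x = X.begin();
  double* o = out.begin();
  const int orow = C * k2;
  for (int n = 0; n < N; ++n) {
    const int in_off = n * H * W;
    const int out_off = n * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int ocol = out_off + wo * Ho + ho;
        double* ocol_p = o + (R_xlen_t)ocol * orow;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            const double* xcol_p = x + (R_xlen_t)(in_off + wi * H + hi) * C;
            const int p = kw * k + kh;
            for (int c = 0; c < C; ++c)
              ocol_p[c * k2 + p] = xcol_p[c];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& cols, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int k2 = k * k;
  NumericMatrix out(C, H * W * N);
  const double* cl = cols.begin();
  double* o = out.begin();
  const int crow = C * k2;
  for (int n = 0; n < N; ++n) {
    const int in_off = n * H * W;
    const int out_off = n * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int ocol = out_off + wo * Ho + ho;
        const double* ccol_p = cl + (R_xlen_t)ocol * crow;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            double* xcol_p = o + (R_xlen_t)(in_off + wi * H + hi) * C;
            const int p = kw * k + kh;
            for (int c = 0; c < C; ++c)
              xcol_p[c] += ccol_p[c * k2 + p];
          }
        }
      }
    }
  }
  return out;
}

// Max pool over valid window positions (padding acts as -Inf).
// Returns the pooled map and, per element, the 1-based input column index of
// the selected maximum (ties -> first in scan order), for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericMatrix& X, int H, int W, int N,
                     int k, int stride, int pad) {
  const int C = X.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C, Ho * Wo * N);
  IntegerMatrix arg(C, Ho * Wo * N);
  const double* x = X.begin();
  for (int n = 0; n < N; ++n) {
    const int in_off = n * H * W;
    const int out_off = n * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int ocol = out_off + wo * Ho + ho;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          int besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = w0 + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = h0 + kh;
              if (hi < 0 || hi >= H) continue;
              const int icol = in_off + wi * H + hi;
              const double v = x[(R_xlen_t)icol * C + c];
              if (v > best) { best = v; besti = icol; }
            }
          }
          out(c, ocol) = best;
          arg(c, ocol) = besti + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& dout, const IntegerMatrix& arg,
                              int ncol_in) {
  const int C = dout.nrow();
  const int M = dout.ncol();
  NumericMatrix dx(C, ncol_in);
  for (int j = 0; j < M; ++j)
    for (int c = 0; c < C; ++c)
      dx(c, arg(c, j) - 1) += dout(c, j);
  return dx;
}

// Depthwise k x k convolution, stride 1, same padding: one k^2 filter per
// channel. W is k^2 x C (patch position fastest), b length C.
// [[Rcpp::export]]
NumericMatrix cpp_depthwise_fwd(const NumericMatrix& X, int H, int W, int N,
                                int k, const NumericMatrix& Wt,
                                const NumericVector& b) {
  const int C = X.nrow();
  const int pad = (k - 1) / 2;
  NumericMatrix out(C, H * W * N);
  const double* x = X.begin();
  const double* w = Wt.begin();
  double* o = out.begin();
  for (int n = 0; n < N; ++n) {
    const int off = n * H * W;
    for (int wo = 0; wo < W; ++wo) {
      for (int ho = 0; ho < H; ++ho) {
        double* ocol = o + (R_xlen_t)(off + wo * H + ho) * C;
        const int h0 = ho - pad, w0 = wo - pad;
        for (int c = 0; c < C; ++c) ocol[c] = b[c];
        for (int kw = 0; kw < k; ++kw) {
          const int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            const double* xcol = x + (R_xlen_t)(off + wi * H + hi) * C;
            const double* wp = w + (kw * k + kh);
            for (int c = 0; c < C; ++c)
              ocol[c] += xcol[c] * wp[(R_xlen_t)c * k * k];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_depthwise_bwd(const NumericMatrix& dout, const NumericMatrix& X,
                       int H, int W, int N, int k, const NumericMatrix& Wt) {
  const int C = X.nrow();
  const int pad = (k - 1) / 2;
  NumericMatrix dX(C, H * W * N);
  NumericMatrix dW(k * k, C);
  NumericVector db(C);
  const double* x = X.begin();
  const double* do_ = dout.begin();
  const double* w = Wt.begin();
  double* dx = dX.begin();
  double* dw = dW.begin();
  for (int n = 0; n < N; ++n) {
    const int off = n * H * W;
    for (int wo = 0; wo < W; ++wo) {
      for (int ho = 0; ho < H; ++ho) {
        const double* dcol = do_ + (R_xlen_t)(off + wo * H + ho) * C;
        const int h0 = ho - pad, w0 = wo - pad;
        for (int c = 0; c < C; ++c) db[c] += dcol[c];
        for (int kw = 0; kw < k; ++kw) {
          const int wi = w0 + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = h0 + kh;
            if (hi < 0 || hi >= H) continue;
            const R_xlen_t icol = (R_xlen_t)(off + wi * H + hi) * C;
            const int p = kw * k + kh;
            for (int c = 0; c < C; ++c) {
              dx[icol + c] += dcol[c] * w[(R_xlen_t)c * k * k + p];
              dw[(R_xlen_t)c * k * k + p] += dcol[c] * x[icol + c];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dX, _["dW"] = dW, _["db"] = db);
}
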