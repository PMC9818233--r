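// Convolution and pooling kernels for the residual-network classifier.
// Tensors use R's column-major array layout: activations (H, W, C, N),
// convolution weights (kh, kw, C_in, C_out). Convolutions are expressed
// as im2col + GEMM so the heavy lifting happens in BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int oH, int oW, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int ow = 0; ow < oW; ++ow) {
          int win = ow * stride - pad + j;
          if (win < 0 || win >= W) continue;
          for (int oh = 0; oh < oH; ++oh) {
            int hin = oh * stride - pad + i;
            if (hin < 0 || hin >= H) continue;
            col(r, oh + (size_t)oH * ow) = xc[hin + (size_t)H * win];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int oH, int oW, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int ow = 0; ow < oW; ++ow) {
          int win = ow * stride - pad + j;
          if (win < 0 || win >= W) continue;
          for (int oh = 0; oh < oH; ++oh) {
            int hin = oh * stride - pad + i;
            if (hin < 0 || hin >= H) continue;
            xc[hin + (size_t)H * win] += col(r, oh + (size_t)oH * ow);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cw = wd[2], O = wd[3];
  if (Cw != C) stop("channel mismatch: input has %d, kernel expects %d", C, Cw);
  int oH = (H + 2 * pad - kh) / stride + 1;
  int oW = (W + 2 * pad - kw) / stride + 1;
  NumericVector y((size_t)oH * oW * O * N);
  y.attr("dim") = IntegerVector::create(oH, oW, O, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, O, false);
  arma::mat col((size_t)kh * kw * C, (size_t)oH * oW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           oH, oW, col);
    arma::mat out = Wm.t() * col;  // O x (oH*oW)
    double* yn = y.begin() + (size_t)oH * oW * O * n;
    for (int o = 0; o < O; ++o)
      for (size_t p = 0; p < (size_t)oH * oW; ++p)
        yn[p + (size_t)oH * oW * o] = out(o, p);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], O = wd[3];
  int oH = (H + 2 * pad - kh) / stride + 1;
  int oW = (W + 2 * pad - kw) / stride + 1;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((size_t)kh * kw * C * O);
  dw.attr("dim") = IntegerVector::create(kh, kw, C, O);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, O, false);
  arma::mat dWm(dw.begin(), (size_t)kh * kw * C, O, false);
  arma::mat col((size_t)kh * kw * C, (size_t)oH * oW);
  arma::mat dym(O, (size_t)oH * oW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           oH, oW, col);
    const double* dyn = dy.begin() + (size_t)oH * oW * O * n;
    for (int o = 0; o < O; ++o)
      for (size_t p = 0; p < (size_t)oH * oW; ++p)
        dym(o, p) = dyn[p + (size_t)oH * oW * o];
    dWm += col * dym.t();
    arma::mat dcol = Wm * dym;
    col2im_add(dcol, H, W, C, kh, kw, stride, pad, oH, oW,
               dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(Named("dx") = dx, Named("dw") = dw);
}

// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)oH * oW * C * N);
  y.attr("dim") = IntegerVector::create(oH, oW, C, N);
  IntegerVector idx((size_t)oH * oW * C * N);
  idx.attr("dim") = IntegerVector::create(oH, oW, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* yn = y.begin() + (size_t)oH * oW * C * n;
    int* in = idx.begin() + (size_t)oH * oW * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (size_t)H * W * c;
      for (int ow = 0; ow < oW; ++ow) {
        for (int oh = 0; oh < oH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int j = 0; j < k; ++j) {
            int win = ow * stride - pad + j;
            if (win < 0 || win >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hin = oh * stride - pad + i;
              if (hin < 0 || hin >= H) continue;
              double v = xc[hin + (size_t)H * win];
              if (v > best) { best = v; besti = hin + H * win; }
            }
          }
          size_t op = oh + (size_t)oH * (ow + (size_t)oW * c);
          yn[op] = (besti >= 0) ? best : 0.0;
          in[op] = besti;  // within-sample linear index incl. channel offset
          if (besti >= 0) in[op] = besti + H * W * c;
        }
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward_cpp(IntegerVector idx, NumericVector dy,
                                   IntegerVector x_dim) {
  int H = x_dim[0], W = x_dim[1], C = x_dim[2], N = x_dim[3];
  IntegerVector yd = dy.attr("dim");
  size_t per_out = (size_t)yd[0] * yd[1] * yd[2];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + per_out * n;
    const int* in = idx.begin() + per_out * n;
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    for (size_t p = 0; p < per_out; ++p)
      if (in[p] >= 0) dxn[in[p]] += dyn[p];
  }
  return dx;
}
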