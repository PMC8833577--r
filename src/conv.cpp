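// Batched 2-D convolution and max-pooling primitives for the CNN classifiers.
// Arrays follow R's column-major layout: images are H x W x C x N, filters
// kh x kw x C x OC.  Convolution is realized as im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col_one(const double* xp, int H, int W, int C,
                            int kh, int kw, int stride, int pad,
                            int OH, int OW) {
  arma::mat cols(kh * kw * C, OH * OW, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          int wsrc = ow * stride - pad + j;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int oh = 0; oh < OH; ++oh) {
            int hsrc = oh * stride - pad + i;
            if (hsrc < 0 || hsrc >= H) continue;
            cols(r, oh + OH * ow) = xc[hsrc + (size_t)H * wsrc];
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_one(const arma::mat& cols, double* xp, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int OH, int OW) {
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          int wsrc = ow * stride - pad + j;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int oh = 0; oh < OH; ++oh) {
            int hsrc = oh * stride - pad + i;
            if (hsrc < 0 || hsrc >= H) continue;
            xc[hsrc + (size_t)H * wsrc] += cols(r, oh + OH * ow);
          }
        }
      }
    }
  }
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], OC = wd[3];
  if (wd[2] != C) stop("filter channel mismatch");
  int OH = (H + 2 * pad - kh) / stride + 1;
  int OW = (W + 2 * pad - kw) / stride + 1;
  if (OH < 1 || OW < 1) stop("input size incompatible with kernel/stride");
  arma::mat W2(w.begin(), kh * kw * C, OC, false);
  NumericVector y = alloc4(OH, OW, OC, N);
  for (int n = 0; n < N; ++n) {
    arma::mat cols = im2col_one(x.begin() + (size_t)H * W * C * n,
                                H, W, C, kh, kw, stride, pad, OH, OW);
    arma::mat out = W2.t() * cols;  // OC x (OH*OW)
    double* yp = y.begin() + (size_t)OH * OW * OC * n;
    for (int oc = 0; oc < OC; ++oc) {
      double bb = b[oc];
      for (int t = 0; t < OH * OW; ++t)
        yp[t + (size_t)OH * OW * oc] = out(oc, t) + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 int stride, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], OC = wd[3];
  int OH = yd[0], OW = yd[1];
  arma::mat W2(w.begin(), kh * kw * C, OC, false);
  arma::mat dW(kh * kw * C, OC, arma::fill::zeros);
  arma::vec db(OC, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    arma::mat cols = im2col_one(x.begin() + (size_t)H * W * C * n,
                                H, W, C, kh, kw, stride, pad, OH, OW);
    arma::mat dYm(OC, OH * OW);
    const double* dp = dy.begin() + (size_t)OH * OW * OC * n;
    for (int oc = 0; oc < OC; ++oc)
      for (int t = 0; t < OH * OW; ++t)
        dYm(oc, t) = dp[t + (size_t)OH * OW * oc];
    dW += cols * dYm.t();
    db += arma::sum(dYm, 1);
    if (need_dx) {
      arma::mat dcols = W2 * dYm;  // K x OH*OW
      col2im_one(dcols, dx.begin() + (size_t)H * W * C * n,
                 H, W, C, kh, kw, stride, pad, OH, OW);
    }
  }
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  List out = List::create(_["dw"] = dwv,
                          _["db"] = NumericVector(db.begin(), db.end()));
  if (need_dx) out["dx"] = dx;
  return out;
}

// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = (H + 2 * pad - k) / stride + 1;
  int OW = (W + 2 * pad - k) / stride + 1;
  NumericVector y = alloc4(OH, OW, C, N);
  IntegerVector arg = alloc4i(OH, OW, C, N);  // flat index into x plane
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)OH * OW * (c + (size_t)C * n);
      int* ap = arg.begin() + (size_t)OH * OW * (c + (size_t)C * n);
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int j = 0; j < k; ++j) {
            int wsrc = ow * stride - pad + j;
            if (wsrc < 0 || wsrc >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hsrc = oh * stride - pad + i;
              if (hsrc < 0 || hsrc >= H) continue;
              double v = xp[hsrc + (size_t)H * wsrc];
              if (v > best) { best = v; besti = hsrc + H * wsrc; }
            }
          }
          yp[oh + (size_t)OH * ow] = best;
          ap[oh + (size_t)OH * ow] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(NumericVector dy, IntegerVector argmax,
                             IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  int OH = yd[0], OW = yd[1];
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dp = dy.begin() + (size_t)OH * OW * (c + (size_t)C * n);
      const int* ap = argmax.begin() + (size_t)OH * OW * (c + (size_t)C * n);
      double* xp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int t = 0; t < OH * OW; ++t)
        if (ap[t] >= 0) xp[ap[t]] += dp[t];
    }
  }
  return dx;
}
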