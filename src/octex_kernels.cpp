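#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim c(H, W, B, C) (column-major, H fastest).
// im2col unrolls kh x kw patches so a convolution becomes one gemm:
//   rows index (oh, ow, b), columns index (i, j, c).

// [[Rcpp::export]]
NumericMatrix octex_im2col(NumericVector x, int H, int W, int B, int C,
                           int kh, int kw, int stride, int pad) {
  const int oH = (H + 2 * pad - kh) / stride + 1;
  const int oW = (W + 2 * pad - kw) / stride + 1;
  const int nrow = oH * oW * B;
  NumericMatrix M(nrow, kh * kw * C);
  const double *px = x.begin();
  double *pm = M.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        double *dst = pm + (R_xlen_t)nrow * col;
        for (int b = 0; b < B; ++b) {
          const double *src = px + (R_xlen_t)H * W * (b + (R_xlen_t)B * c);
          for (int ow = 0; ow < oW; ++ow) {
            const int w = ow * stride - pad + j;
            const R_xlen_t rbase = oH * (ow + (R_xlen_t)oW * b);
            if (w < 0 || w >= W) {
              for (int oh = 0; oh < oH; ++oh) dst[rbase + oh] = 0.0;
            } else {
              for (int oh = 0; oh < oH; ++oh) {
                const int h = oh * stride - pad + i;
                dst[rbase + oh] =
                    (h < 0 || h >= H) ? 0.0 : src[h + (R_xlen_t)H * w];
              }
            }
          }
        }
      }
    }
  }
  return M;
}

// Adjoint of im2col: scatter-adds column gradients back onto the image grid.
// [[Rcpp::export]]
NumericVector octex_col2im(NumericMatrix M, int H, int W, int B, int C,
                           int kh, int kw, int stride, int pad) {
  const int oH = (H + 2 * pad - kh) / stride + 1;
  const int oW = (W + 2 * pad - kw) / stride + 1;
  const int nrow = oH * oW * B;
  NumericVector x((R_xlen_t)H * W * B * C);
  double *px = x.begin();
  const double *pm = M.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        const double *src = pm + (R_xlen_t)nrow * col;
        for (int b = 0; b < B; ++b) {
          double *dst = px + (R_xlen_t)H * W * (b + (R_xlen_t)B * c);
          for (int ow = 0; ow < oW; ++ow) {
            const int w = ow * stride - pad + j;
            if (w < 0 || w >= W) continue;
            const R_xlen_t rbase = oH * (ow + (R_xlen_t)oW * b);
            for (int oh = 0; oh < oH; ++oh) {
              const int h = oh * stride - pad + i;
              if (h < 0 || h >= H) continue;
              dst[h + (R_xlen_t)H * w] += src[rbase + oh];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, B, C);
  return x;
}

// Max pooling; records the winning input index (1-based, per full tensor)
// so the backward pass is a scatter-add.
// [[Rcpp::export]]
List octex_maxpool(NumericVector x, int H, int W, int B, int C,
                   int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)oH * oW * B * C);
  IntegerVector arg((R_xlen_t)oH * oW * B * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const R_xlen_t ibase = (R_xlen_t)H * W * (b + (R_xlen_t)B * c);
      const R_xlen_t obase = (R_xlen_t)oH * oW * (b + (R_xlen_t)B * c);
      for (int ow = 0; ow < oW; ++ow) {
        for (int oh = 0; oh < oH; ++oh) {
          double best = R_NegInf;
          R_xlen_t bestidx = -1;
          for (int j = 0; j < k; ++j) {
            const int w = ow * stride - pad + j;
            if (w < 0 || w >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int h = oh * stride - pad + i;
              if (h < 0 || h >= H) continue;
              const double v = px[ibase + h + (R_xlen_t)H * w];
              if (v > best) { best = v; bestidx = ibase + h + (R_xlen_t)H * w; }
            }
          }
          const R_xlen_t o = obase + oh + (R_xlen_t)oH * ow;
          y[o] = best;
          arg[o] = (int)(bestidx + 1);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oH, oW, B, C);
  return List::create(_["out"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector octex_maxpool_backward(NumericVector dy, IntegerVector argmax,
                                     int H, int W, int B, int C) {
  NumericVector dx((R_xlen_t)H * W * B * C);
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  for (R_xlen_t o = 0; o < dy.size(); ++o) pdx[argmax[o] - 1] += pdy[o];
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  return dx;
}

// Fused batch-norm forward over an (n x C) column-contiguous matrix view.
// Returns y, xhat, invstd and the updated running statistics.
// [[Rcpp::export]]
List octex_bn_fwd(NumericVector x, int n, int C, NumericVector gamma,
                  NumericVector beta, NumericVector rmean, NumericVector rvar,
                  bool training, double momentum, double eps) {
  NumericVector y(x.size()), xhat(x.size()), invstd(C);
  NumericVector rm = clone(rmean), rv = clone(rvar);
  for (int c = 0; c < C; ++c) {
    const double *px = x.begin() + (R_xlen_t)n * c;
    double mu, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int i = 0; i < n; ++i) s += px[i];
      mu = s / n;
      for (int i = 0; i < n; ++i) { double d = px[i] - mu; s2 += d * d; }
      var = s2 / n;
      rm[c] = (1 - momentum) * rm[c] + momentum * mu;
      rv[c] = (1 - momentum) * rv[c] +
              momentum * var * n / (n > 1 ? n - 1 : 1);
    } else {
      mu = rmean[c];
      var = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    double *ph = xhat.begin() + (R_xlen_t)n * c;
    double *py = y.begin() + (R_xlen_t)n * c;
    for (int i = 0; i < n; ++i) {
      const double xh = (px[i] - mu) * is;
      ph[i] = xh;
      py[i] = g * xh + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rmean"] = rm, _["rvar"] = rv);
}

// [[Rcpp::export]]
List octex_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector invstd,
                  NumericVector gamma, int n, int C, bool training) {
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *pdy = dy.begin() + (R_xlen_t)n * c;
    const double *ph = xhat.begin() + (R_xlen_t)n * c;
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) { sg += pdy[i] * ph[i]; sb += pdy[i]; }
    dgamma[c] = sg;
    dbeta[c] = sb;
    double *pdx = dx.begin() + (R_xlen_t)n * c;
    const double g = gamma[c], is = invstd[c];
    if (training) {
      const double m1 = sb / n, m2 = sg / n;
      for (int i = 0; i < n; ++i) {
        pdx[i] = g * is * (pdy[i] - m1 - ph[i] * m2);
      }
    } else {
      for (int i = 0; i < n; ++i) pdx[i] = g * is * pdy[i];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List octex_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  LogicalVector mask(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const bool pos = x[i] > 0;
    mask[i] = pos;
    y[i] = pos ? x[i] : 0.0;
  }
  return List::create(_["y"] = y, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericVector octex_relu_bwd(NumericVector dy, LogicalVector mask) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = mask[i] ? dy[i] : 0.0;
  return dx;
}
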