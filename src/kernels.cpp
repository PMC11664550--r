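// Low-level numerical kernels for the detector.
//
// All feature maps are R arrays of dim (H, W, C), column-major, so element
// (h, w, c) [0-based] sits at h + H*(w + W*c).  Dense convolutions use an
// im2col + BLAS matrix product; the im2col row for output position
// n = ho + Hout*wo has columns indexed q = dh + kh*(dw + kw*ci), which fixes
// the weight layout to a (kh*kw*cin) x cout matrix shared with the R side
// (initialisation, audit, reparameterization).

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static arma::mat im2col(const double* x, int H, int W, int C,
                        int kh, int kw, int stride, int pad,
                        int Hout, int Wout) {
  arma::mat col(Hout * (long)Wout, (long)kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        long q = dh + kh * ((long)dw + kw * (long)c);
        for (int wo = 0; wo < Wout; ++wo) {
          int wi = wo * stride + dw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Hout; ++ho) {
            int hi = ho * stride + dh - pad;
            if (hi < 0 || hi >= H) continue;
            col(ho + (long)Hout * wo, q) = x[hi + (long)H * (wi + (long)W * c)];
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xdim,
                            NumericMatrix wt, int kh, int kw,
                            int stride, int pad, NumericVector bias) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int Cout = wt.ncol();
  int Hout = out_size(H, kh, stride, pad), Wout = out_size(W, kw, stride, pad);
  arma::mat col = im2col(x.begin(), H, W, C, kh, kw, stride, pad, Hout, Wout);
  arma::mat Wm(wt.begin(), wt.nrow(), Cout, false);
  arma::mat y = col * Wm;
  if (bias.size() == (R_xlen_t)Cout) {
    for (int c = 0; c < Cout; ++c) y.col(c) += bias[c];
  }
  NumericVector out(y.memptr(), y.memptr() + y.n_elem);
  out.attr("dim") = IntegerVector::create(Hout, Wout, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xdim,
                   NumericMatrix wt, int kh, int kw, int stride, int pad,
                   NumericVector gy, bool has_bias) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int Cout = wt.ncol();
  int Hout = out_size(H, kh, stride, pad), Wout = out_size(W, kw, stride, pad);
  long N = (long)Hout * Wout;
  arma::mat col = im2col(x.begin(), H, W, C, kh, kw, stride, pad, Hout, Wout);
  arma::mat Gy((double*)gy.begin(), N, Cout, false);
  arma::mat Wm(wt.begin(), wt.nrow(), Cout, false);
  arma::mat gW = col.t() * Gy;                 // (kh*kw*C) x Cout
  arma::mat gcol = Gy * Wm.t();                // N x (kh*kw*C)
  NumericVector gx(x.size());
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        long q = dh + kh * ((long)dw + kw * (long)c);
        for (int wo = 0; wo < Wout; ++wo) {
          int wi = wo * stride + dw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Hout; ++ho) {
            int hi = ho * stride + dh - pad;
            if (hi < 0 || hi >= H) continue;
            gxp[hi + (long)H * (wi + (long)W * c)] += gcol(ho + (long)Hout * wo, q);
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  NumericMatrix gWout(gW.n_rows, gW.n_cols);
  std::copy(gW.memptr(), gW.memptr() + gW.n_elem, gWout.begin());
  List res = List::create(_["gx"] = gx, _["gw"] = gWout);
  if (has_bias) {
    NumericVector gb(Cout);
    for (int c = 0; c < Cout; ++c) gb[c] = arma::accu(Gy.col(c));
    res["gb"] = gb;
  }
  return res;
}

// Depthwise convolution: one kh x kw kernel per channel, weights as a
// (kh*kw) x C matrix with row index dh + kh*dw.
// [[Rcpp::export]]
NumericVector cpp_dwconv_fw(NumericVector x, IntegerVector xdim,
                            NumericMatrix wt, int kh, int kw,
                            int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int Hout = out_size(H, kh, stride, pad), Wout = out_size(W, kw, stride, pad);
  NumericVector y((long)Hout * Wout * C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        double acc = 0.0;
        for (int dw = 0; dw < kw; ++dw) {
          int wi = wo * stride + dw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int hi = ho * stride + dh - pad;
            if (hi < 0 || hi >= H) continue;
            acc += xp[hi + (long)H * (wi + (long)W * c)] * wt(dh + kh * dw, c);
          }
        }
        yp[ho + (long)Hout * (wo + (long)Wout * c)] = acc;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Hout, Wout, C);
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bw(NumericVector x, IntegerVector xdim,
                   NumericMatrix wt, int kh, int kw, int stride, int pad,
                   NumericVector gy) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int Hout = out_size(H, kh, stride, pad), Wout = out_size(W, kw, stride, pad);
  NumericVector gx(x.size());
  NumericMatrix gw(kh * kw, C);
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        double g = gyp[ho + (long)Hout * (wo + (long)Wout * c)];
        if (g == 0.0) continue;
        for (int dw = 0; dw < kw; ++dw) {
          int wi = wo * stride + dw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            int hi = ho * stride + dh - pad;
            if (hi < 0 || hi >= H) continue;
            long xi = hi + (long)H * (wi + (long)W * c);
            gx[xi] = gxp[xi] + g * wt(dh + kh * dw, c);
            gw(dh + kh * dw, c) += g * xp[xi];
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Max pooling with "same"-style zero-free padding semantics: window positions
// outside the input are ignored (never win the max).
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, IntegerVector xdim,
                    int k, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int Hout = out_size(H, k, stride, pad), Wout = out_size(W, k, stride, pad);
  NumericVector y((long)Hout * Wout * C);
  IntegerVector arg((long)Hout * Wout * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        double best = R_NegInf; long besti = -1;
        for (int dw = 0; dw < k; ++dw) {
          int wi = wo * stride + dw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            int hi = ho * stride + dh - pad;
            if (hi < 0 || hi >= H) continue;
            long xi = hi + (long)H * (wi + (long)W * c);
            if (xp[xi] > best) { best = xp[xi]; besti = xi; }
          }
        }
        long oi = ho + (long)Hout * (wo + (long)Wout * c);
        y[oi] = best; arg[oi] = (int)besti;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Hout, Wout, C);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector xdim, IntegerVector argmax,
                             NumericVector gy) {
  NumericVector gx((long)xdim[0] * xdim[1] * xdim[2]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear grid sampling with border clamping.  sx, sy give, for each output
// pixel and offset group, the continuous (column, row) sample coordinate in
// 0-based input pixel units; channels are split into G contiguous groups each
// using its own coordinate field.  Gradients w.r.t. coordinates are zero where
// the coordinate was clamped at the border.
// [[Rcpp::export]]
NumericVector cpp_gridsample_fw(NumericVector x, IntegerVector xdim,
                                NumericVector sx, NumericVector sy,
                                IntegerVector sdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int Hout = sdim[0], Wout = sdim[1], G = sdim[2];
  NumericVector y((long)Hout * Wout * C);
  const double* xp = x.begin();
  int per = C / G;
  for (int c = 0; c < C; ++c) {
    int g = c / per; if (g >= G) g = G - 1;
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        long si = ho + (long)Hout * (wo + (long)Wout * g);
        double cx = clampd(sx[si], 0.0, W - 1.0);
        double cy = clampd(sy[si], 0.0, H - 1.0);
        int x0 = (int)std::floor(cx); if (x0 > W - 2) x0 = W > 1 ? W - 2 : 0;
        int y0 = (int)std::floor(cy); if (y0 > H - 2) y0 = H > 1 ? H - 2 : 0;
        double tx = cx - x0, ty = cy - y0;
        int x1 = W > 1 ? x0 + 1 : x0, y1 = H > 1 ? y0 + 1 : y0;
        double v00 = xp[y0 + (long)H * (x0 + (long)W * c)];
        double v01 = xp[y0 + (long)H * (x1 + (long)W * c)];
        double v10 = xp[y1 + (long)H * (x0 + (long)W * c)];
        double v11 = xp[y1 + (long)H * (x1 + (long)W * c)];
        y[ho + (long)Hout * (wo + (long)Wout * c)] =
          (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Hout, Wout, C);
  return y;
}

// [[Rcpp::export]]
List cpp_gridsample_bw(NumericVector x, IntegerVector xdim,
                       NumericVector sx, NumericVector sy, IntegerVector sdim,
                       NumericVector gy) {
  int H = xdim[0], W = xdim[1], C = xdim[2];
  int Hout = sdim[0], Wout = sdim[1], G = sdim[2];
  NumericVector gx(x.size());
  NumericVector gsx(sx.size()), gsy(sy.size());
  const double* xp = x.begin();
  int per = C / G;
  for (int c = 0; c < C; ++c) {
    int g = c / per; if (g >= G) g = G - 1;
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        long si = ho + (long)Hout * (wo + (long)Wout * g);
        double gout = gy[ho + (long)Hout * (wo + (long)Wout * c)];
        if (gout == 0.0) continue;
        double rx = sx[si], ry = sy[si];
        bool inx = (rx >= 0.0 && rx <= W - 1.0), iny = (ry >= 0.0 && ry <= H - 1.0);
        double cx = clampd(rx, 0.0, W - 1.0), cy = clampd(ry, 0.0, H - 1.0);
        int x0 = (int)std::floor(cx); if (x0 > W - 2) x0 = W > 1 ? W - 2 : 0;
        int y0 = (int)std::floor(cy); if (y0 > H - 2) y0 = H > 1 ? H - 2 : 0;
        double tx = cx - x0, ty = cy - y0;
        int x1 = W > 1 ? x0 + 1 : x0, y1 = H > 1 ? y0 + 1 : y0;
        long i00 = y0 + (long)H * (x0 + (long)W * c);
        long i01 = y0 + (long)H * (x1 + (long)W * c);
        long i10 = y1 + (long)H * (x0 + (long)W * c);
        long i11 = y1 + (long)H * (x1 + (long)W * c);
        gx[i00] += gout * (1 - ty) * (1 - tx);
        gx[i01] += gout * (1 - ty) * tx;
        gx[i10] += gout * ty * (1 - tx);
        gx[i11] += gout * ty * tx;
        if (inx) {
          double dvdx = (1 - ty) * (xp[i01] - xp[i00]) + ty * (xp[i11] - xp[i10]);
          gsx[si] += gout * dvdx;
        }
        if (iny) {
          double dvdy = (1 - tx) * (xp[i10] - xp[i00]) + tx * (xp[i11] - xp[i01]);
          gsy[si] += gout * dvdy;
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  gsx.attr("dim") = sdim;
  gsy.attr("dim") = sdim;
  return List::create(_["gx"] = gx, _["gsx"] = gsx, _["gsy"] = gsy);
}

// y = x * scale[c] + shift[c] over an (H, W, C) array.
// [[Rcpp::export]]
NumericVector cpp_scale_shift(NumericVector x, IntegerVector xdim,
                              NumericVector scale, NumericVector shift) {
  int HW = xdim[0] * xdim[1], C = xdim[2];
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    double s = scale[c], b = shift[c];
    const double* xp = x.begin() + (long)HW * c;
    double* yp = y.begin() + (long)HW * c;
    for (int i = 0; i < HW; ++i) yp[i] = xp[i] * s + b;
  }
  y.attr("dim") = xdim;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_scale_mul(NumericVector g, IntegerVector xdim,
                            NumericVector scale) {
  int HW = xdim[0] * xdim[1], C = xdim[2];
  NumericVector y(g.size());
  for (int c = 0; c < C; ++c) {
    double s = scale[c];
    const double* gp = g.begin() + (long)HW * c;
    double* yp = y.begin() + (long)HW * c;
    for (int i = 0; i < HW; ++i) yp[i] = gp[i] * s;
  }
  y.attr("dim") = xdim;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin(); double* yp = y.begin();
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector x, NumericVector g) {
  NumericVector y(g.size());
  const double* xp = x.begin(); const double* gp = g.begin();
  double* yp = y.begin();
  R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? gp[i] : 0.0;
  y.attr("dim") = g.attr("dim");
  return y;
}

// Training-mode batch norm over H*W per channel (biased variance).
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, IntegerVector xdim, NumericVector gamma,
               NumericVector beta, double eps) {
  int HW = xdim[0] * xdim[1], C = xdim[2];
  NumericVector y(x.size()), mu(C), va(C), inv(C);
  for (int c = 0; c < C; ++c) {
    const double* xp = x.begin() + (long)HW * c;
    double s = 0, s2 = 0;
    for (int i = 0; i < HW; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
    double m = s / HW, v = s2 / HW - m * m;
    if (v < 0) v = 0;
    mu[c] = m; va[c] = v; inv[c] = 1.0 / std::sqrt(v + eps);
    double a = gamma[c] * inv[c], b = beta[c] - m * a;
    double* yp = y.begin() + (long)HW * c;
    for (int i = 0; i < HW; ++i) yp[i] = xp[i] * a + b;
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = va, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, IntegerVector xdim, NumericVector mu,
               NumericVector inv, NumericVector gamma, NumericVector gy) {
  int HW = xdim[0] * xdim[1], C = xdim[2];
  NumericVector gx(x.size()), ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* xp = x.begin() + (long)HW * c;
    const double* gp = gy.begin() + (long)HW * c;
    double sg = 0, sgx = 0;
    for (int i = 0; i < HW; ++i) {
      sg += gp[i];
      sgx += gp[i] * (xp[i] - mu[c]) * inv[c];
    }
    gbeta[c] = sg; ggamma[c] = sgx;
    double a = gamma[c] * inv[c];
    double m1 = sg / HW, m2 = sgx / HW;
    double* gxp = gx.begin() + (long)HW * c;
    for (int i = 0; i < HW; ++i)
      gxp[i] = a * (gp[i] - m1 - (xp[i] - mu[c]) * inv[c] * m2);
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// Scatter-add: out[idx[i]] += g[i] (1-based idx, NA skipped).
// [[Rcpp::export]]
NumericVector cpp_scatter_add(int n, IntegerVector idx, NumericVector g) {
  NumericVector out(n);
  double* op = out.begin();
  const double* gp = g.begin();
  const int* ip = idx.begin();
  R_xlen_t m = idx.size();
  for (R_xlen_t i = 0; i < m; ++i) {
    if (ip[i] == NA_INTEGER) continue;
    op[ip[i] - 1] += gp[i];
  }
  return out;
}

// Expanded-window multi-head self-attention, all windows in one call.
// q, k, v: (H, W, C) maps; planq/plank: per-window 1-based linear spatial
// positions for queries and keys; heads divides C.  Returns the attention
// output (H, W, C) plus the softmax matrices for the backward pass.
// [[Rcpp::export]]
List cpp_ewmhsa_fw(NumericVector q, NumericVector k, NumericVector v,
                   IntegerVector xdim, List planq, List plank, int heads) {
  int HW = xdim[0] * xdim[1], C = xdim[2];
  int dh = C / heads;
  double sc = 1.0 / std::sqrt((double)dh);
  arma::mat qm((double*)q.begin(), HW, C, false);
  arma::mat km((double*)k.begin(), HW, C, false);
  arma::mat vm((double*)v.begin(), HW, C, false);
  arma::mat om(HW, C, arma::fill::zeros);
  int nw = planq.size();
  List Ps(nw * heads);
  for (int i = 0; i < nw; ++i) {
    IntegerVector pq = planq[i], pk = plank[i];
    arma::uvec uq(pq.size()), uk(pk.size());
    for (int j = 0; j < pq.size(); ++j) uq[j] = pq[j] - 1;
    for (int j = 0; j < pk.size(); ++j) uk[j] = pk[j] - 1;
    for (int h = 0; h < heads; ++h) {
      arma::uvec cols = arma::regspace<arma::uvec>(h * dh, (h + 1) * dh - 1);
      arma::mat Qh = qm.submat(uq, cols);
      arma::mat Kh = km.submat(uk, cols);
      arma::mat A = Qh * Kh.t() * sc;
      A.each_col() -= arma::max(A, 1);
      arma::mat P = arma::exp(A);
      arma::vec rs = arma::sum(P, 1);
      P.each_col() /= rs;
      arma::mat Oh = P * vm.submat(uk, cols);
      om.submat(uq, cols) = Oh;
      NumericMatrix Pm(P.n_rows, P.n_cols);
      std::copy(P.memptr(), P.memptr() + P.n_elem, Pm.begin());
      Ps[i * heads + h] = Pm;
    }
  }
  NumericVector out(om.memptr(), om.memptr() + om.n_elem);
  out.attr("dim") = xdim;
  return List::create(_["y"] = out, _["P"] = Ps);
}

// [[Rcpp::export]]
List cpp_ewmhsa_bw(NumericVector q, NumericVector k, NumericVector v,
                   IntegerVector xdim, List planq, List plank, int heads,
                   List Ps, NumericVector gy) {
  int HW = xdim[0] * xdim[1], C = xdim[2];
  int dh = C / heads;
  double sc = 1.0 / std::sqrt((double)dh);
  arma::mat qm((double*)q.begin(), HW, C, false);
  arma::mat km((double*)k.begin(), HW, C, false);
  arma::mat vm((double*)v.begin(), HW, C, false);
  arma::mat gm((double*)gy.begin(), HW, C, false);
  arma::mat gq(HW, C, arma::fill::zeros), gk(HW, C, arma::fill::zeros),
            gv(HW, C, arma::fill::zeros);
  int nw = planq.size();
  for (int i = 0; i < nw; ++i) {
    IntegerVector pq = planq[i], pk = plank[i];
    arma::uvec uq(pq.size()), uk(pk.size());
    for (int j = 0; j < pq.size(); ++j) uq[j] = pq[j] - 1;
    for (int j = 0; j < pk.size(); ++j) uk[j] = pk[j] - 1;
    for (int h = 0; h < heads; ++h) {
      arma::uvec cols = arma::regspace<arma::uvec>(h * dh, (h + 1) * dh - 1);
      NumericMatrix Pm = Ps[i * heads + h];
      arma::mat P((double*)Pm.begin(), Pm.nrow(), Pm.ncol(), false);
      arma::mat gO = gm.submat(uq, cols);
      arma::mat Vh = vm.submat(uk, cols);
      arma::mat gP = gO * Vh.t();
      gv.submat(uk, cols) += P.t() * gO;
      arma::vec rs = arma::sum(gP % P, 1);
      arma::mat gA = P % (gP.each_col() - rs) * sc;
      gq.submat(uq, cols) += gA * km.submat(uk, cols);
      gk.submat(uk, cols) += gA.t() * qm.submat(uq, cols);
    }
  }
  NumericVector rq(gq.memptr(), gq.memptr() + gq.n_elem);
  NumericVector rk(gk.memptr(), gk.memptr() + gk.n_elem);
  NumericVector rv(gv.memptr(), gv.memptr() + gv.n_elem);
  rq.attr("dim") = xdim; rk.attr("dim") = xdim; rv.attr("dim") = xdim;
  return List::create(_["gq"] = rq, _["gk"] = rk, _["gv"] = rv);
}
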