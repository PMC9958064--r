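// Convolution forward/backward kernels for the model-graph executor.
// Layout convention: feature tensors are column-major R arrays with
// dim = c(H, W, C, N); conv weights are c(k, k, C_in, C_out); depthwise
// weights are c(k, k, C, Psi) with output channel o = c * Psi + psi.
// "Same" padding with pad = (k - 1) / 2 (odd kernels only).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int H, int k, int pad, int stride) {
  return (H + 2 * pad - k) / stride + 1;
}

// im2col over the whole batch: (k*k*C) x (OH*OW*N); column index
// oh + OH*(ow + OW*n), row index ki + k*(kj + k*c).
static arma::mat im2col_batch(const double* x, int H, int W, int C, int N,
                              int k, int pad, int stride, int OH, int OW) {
  arma::mat M(k * k * C, (arma::uword)OH * OW * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)H * W * C * n;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        arma::uword col = oh + (arma::uword)OH * (ow + (arma::uword)OW * n);
        double* Mcol = M.colptr(col);
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (size_t)H * W * c;
          for (int kj = 0; kj < k; ++kj) {
            int wj = ow * stride - pad + kj;
            bool win = (wj >= 0 && wj < W);
            for (int ki = 0; ki < k; ++ki) {
              int hi = oh * stride - pad + ki;
              double v = 0.0;
              if (win && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wj];
              Mcol[ki + k * (kj + k * c)] = v;
            }
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add of a column matrix back onto the input tensor (gradient of
// im2col_batch).
static void col2im_batch(const arma::mat& M, double* dx, int H, int W, int C,
                         int N, int k, int pad, int stride, int OH, int OW) {
  for (int n = 0; n < N; ++n) {
    double* xn = dx + (size_t)H * W * C * n;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        arma::uword col = oh + (arma::uword)OH * (ow + (arma::uword)OW * n);
        const double* Mcol = M.colptr(col);
        for (int c = 0; c < C; ++c) {
          double* xc = xn + (size_t)H * W * c;
          for (int kj = 0; kj < k; ++kj) {
            int wj = ow * stride - pad + kj;
            bool win = (wj >= 0 && wj < W);
            for (int ki = 0; ki < k; ++ki) {
              int hi = oh * stride - pad + ki;
              if (win && hi >= 0 && hi < H)
                xc[hi + (size_t)H * wj] += Mcol[ki + k * (kj + k * c)];
            }
          }
        }
      }
    }
  }
}

// Single-channel im2col: (k*k) x (OH*OW*N).
static arma::mat im2col_chan(const double* x, int H, int W, int C, int N,
                             int c, int k, int pad, int stride, int OH,
                             int OW) {
  arma::mat M(k * k, (arma::uword)OH * OW * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xc = x + (size_t)H * W * C * n + (size_t)H * W * c;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        arma::uword col = oh + (arma::uword)OH * (ow + (arma::uword)OW * n);
        double* Mcol = M.colptr(col);
        for (int kj = 0; kj < k; ++kj) {
          int wj = ow * stride - pad + kj;
          bool win = (wj >= 0 && wj < W);
          for (int ki = 0; ki < k; ++ki) {
            int hi = oh * stride - pad + ki;
            double v = 0.0;
            if (win && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wj];
            Mcol[ki + k * kj] = v;
          }
        }
      }
    }
  }
  return M;
}

static void col2im_chan(const arma::mat& M, double* dx, int H, int W, int C,
                        int N, int c, int k, int pad, int stride, int OH,
                        int OW) {
  for (int n = 0; n < N; ++n) {
    double* xc = dx + (size_t)H * W * C * n + (size_t)H * W * c;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        arma::uword col = oh + (arma::uword)OH * (ow + (arma::uword)OW * n);
        const double* Mcol = M.colptr(col);
        for (int kj = 0; kj < k; ++kj) {
          int wj = ow * stride - pad + kj;
          bool win = (wj >= 0 && wj < W);
          for (int ki = 0; ki < k; ++ki) {
            int hi = oh * stride - pad + ki;
            if (win && hi >= 0 && hi < H)
              xc[hi + (size_t)H * wj] += Mcol[ki + k * kj];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv: weight in_channels do not match input");
  int pad = (k - 1) / 2;
  int OH = out_dim(H, k, pad, stride), OW = out_dim(W, k, pad, stride);
  if (OH < 1 || OW < 1) stop("conv: input too small for kernel/stride");
  arma::mat M = im2col_batch(REAL(x), H, W, C, N, k, pad, stride, OH, OW);
  arma::mat Wm(const_cast<double*>(REAL(w)), k * k * C, Cout, false, true);
  arma::mat Y = Wm.t() * M;  // Cout x (OH*OW*N)
  NumericVector out((R_xlen_t)OH * OW * Cout * N);
  double* o = REAL(out);
  const double* bp = REAL(b);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double bias = bp[co];
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          arma::uword col = oh + (arma::uword)OH * (ow + (arma::uword)OW * n);
          o[oh + (size_t)OH * (ow + (size_t)OW * (co + (size_t)Cout * n))] =
              Y(co, col) + bias;
        }
    }
  out.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int OH = yd[0], OW = yd[1];
  int pad = (k - 1) / 2;
  arma::mat M = im2col_batch(REAL(x), H, W, C, N, k, pad, stride, OH, OW);
  arma::mat dYm(Cout, (arma::uword)OH * OW * N);
  const double* dyp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh)
          dYm(co, oh + (arma::uword)OH * (ow + (arma::uword)OW * n)) =
              dyp[oh + (size_t)OH * (ow + (size_t)OW * (co + (size_t)Cout * n))];
  arma::mat Wm(const_cast<double*>(REAL(w)), k * k * C, Cout, false, true);
  arma::mat dW = M * dYm.t();         // (k*k*C) x Cout
  arma::vec db = arma::sum(dYm, 1);   // Cout
  arma::mat dM = Wm * dYm;            // (k*k*C) x ncol
  NumericVector dx((R_xlen_t)H * W * C * N);
  col2im_batch(dM, REAL(dx), H, W, C, N, k, pad, stride, OH, OW);
  dx.attr("dim") = xd;
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Psi = wd[3];
  if (wd[2] != C) stop("dwconv: weight channels do not match input");
  int pad = (k - 1) / 2;
  int OH = out_dim(H, k, pad, stride), OW = out_dim(W, k, pad, stride);
  if (OH < 1 || OW < 1) stop("dwconv: input too small for kernel/stride");
  int Cout = C * Psi;
  NumericVector out((R_xlen_t)OH * OW * Cout * N);
  double* o = REAL(out);
  const double* wp = REAL(w);
  const double* bp = REAL(b);
  for (int c = 0; c < C; ++c) {
    arma::mat Mc = im2col_chan(REAL(x), H, W, C, N, c, k, pad, stride, OH, OW);
    arma::mat wc(k * k, Psi);
    for (int p = 0; p < Psi; ++p)
      for (int q = 0; q < k * k; ++q)
        wc(q, p) = wp[q + (size_t)k * k * c + (size_t)k * k * C * p];
    arma::mat Yc = wc.t() * Mc;  // Psi x ncol
    for (int p = 0; p < Psi; ++p) {
      int co = c * Psi + p;
      double bias = bp[co];
      for (int n = 0; n < N; ++n)
        for (int ow = 0; ow < OW; ++ow)
          for (int oh = 0; oh < OH; ++oh)
            o[oh + (size_t)OH * (ow + (size_t)OW * (co + (size_t)Cout * n))] =
                Yc(p, oh + (arma::uword)OH * (ow + (arma::uword)OW * n)) + bias;
    }
  }
  out.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Psi = wd[3];
  int OH = yd[0], OW = yd[1];
  int pad = (k - 1) / 2;
  int Cout = C * Psi;
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dW((R_xlen_t)k * k * C * Psi);
  NumericVector db(Cout);
  const double* dyp = REAL(dy);
  const double* wp = REAL(w);
  for (int c = 0; c < C; ++c) {
    arma::mat Mc = im2col_chan(REAL(x), H, W, C, N, c, k, pad, stride, OH, OW);
    arma::mat dYc(Psi, (arma::uword)OH * OW * N);
    for (int p = 0; p < Psi; ++p) {
      int co = c * Psi + p;
      double s = 0.0;
      for (int n = 0; n < N; ++n)
        for (int ow = 0; ow < OW; ++ow)
          for (int oh = 0; oh < OH; ++oh) {
            double v = dyp[oh + (size_t)OH *
                                    (ow + (size_t)OW * (co + (size_t)Cout * n))];
            dYc(p, oh + (arma::uword)OH * (ow + (arma::uword)OW * n)) = v;
            s += v;
          }
      db[co] = s;
    }
    arma::mat dwc = Mc * dYc.t();  // (k*k) x Psi
    for (int p = 0; p < Psi; ++p)
      for (int q = 0; q < k * k; ++q)
        dW[q + (size_t)k * k * c + (size_t)k * k * C * p] = dwc(q, p);
    arma::mat wc(k * k, Psi);
    for (int p = 0; p < Psi; ++p)
      for (int q = 0; q < k * k; ++q)
        wc(q, p) = wp[q + (size_t)k * k * c + (size_t)k * k * C * p];
    arma::mat dMc = wc * dYc;
    col2im_chan(dMc, REAL(dx), H, W, C, N, c, k, pad, stride, OH, OW);
  }
  dx.attr("dim") = xd;
  dW.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dW, _["db"] = db);
}

// ---- Fused element-wise helpers (avoid R temporaries) ----

// y = x * a[c] + b[c] with per-channel a, b over an H x W x C x N array.
// [[Rcpp::export]]
NumericVector cpp_scale_shift(NumericVector x, NumericVector a,
                              NumericVector b) {
  IntegerVector xd = x.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector out(x.size());
  const double* xp = REAL(x);
  double* o = REAL(out);
  const double* ap = REAL(a);
  const double* bp = REAL(b);
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double ac = ap[c], bc = bp[c];
      for (size_t j = 0; j < HW; ++j, ++i) o[i] = xp[i] * ac + bc;
    }
  out.attr("dim") = xd;
  return out;
}

// Per-channel sums over H, W, N of x and of x * y (y optional):
// returns a C x 2 matrix [sum_x, sum_xy].
// [[Rcpp::export]]
NumericMatrix cpp_channel_sums2(NumericVector x, NumericVector y) {
  IntegerVector xd = x.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  bool with_y = y.size() == x.size();
  NumericMatrix out(C, 2);
  const double* xp = REAL(x);
  const double* yp = with_y ? REAL(y) : nullptr;
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s1 = 0.0, s2 = 0.0;
      if (with_y) {
        for (size_t j = 0; j < HW; ++j, ++i) {
          s1 += xp[i];
          s2 += xp[i] * yp[i];
        }
      } else {
        for (size_t j = 0; j < HW; ++j, ++i) s1 += xp[i];
      }
      out(c, 0) += s1;
      out(c, 1) += s2;
    }
  return out;
}

// Batch-norm input gradient: dx = dy * a[c] - t1[c] - xhat * t2[c].
// [[Rcpp::export]]
NumericVector cpp_bn_bwd_dx(NumericVector dy, NumericVector xhat,
                            NumericVector a, NumericVector t1,
                            NumericVector t2) {
  IntegerVector xd = dy.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector out(dy.size());
  const double* dp = REAL(dy);
  const double* hp = REAL(xhat);
  double* o = REAL(out);
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double ac = a[c], u1 = t1[c], u2 = t2[c];
      for (size_t j = 0; j < HW; ++j, ++i) o[i] = dp[i] * ac - u1 - hp[i] * u2;
    }
  out.attr("dim") = xd;
  return out;
}

// Activations in one pass. kind: 0 = swish, 1 = sigmoid, 2 = selu, 3 = relu.
// [[Rcpp::export]]
NumericVector cpp_act_fwd(NumericVector x, int kind) {
  const double lam = 1.0507009873554804934193349852946;
  const double lb = lam * 1.6732632423543772848170429916717;
  NumericVector out(x.size());
  const double* xp = REAL(x);
  double* o = REAL(out);
  R_xlen_t n = x.size();
  switch (kind) {
    case 0: for (R_xlen_t i = 0; i < n; ++i) o[i] = xp[i] / (1.0 + std::exp(-xp[i])); break;
    case 1: for (R_xlen_t i = 0; i < n; ++i) o[i] = 1.0 / (1.0 + std::exp(-xp[i])); break;
    case 2: for (R_xlen_t i = 0; i < n; ++i) o[i] = xp[i] > 0 ? lam * xp[i] : lb * (std::exp(xp[i]) - 1.0); break;
    case 3: for (R_xlen_t i = 0; i < n; ++i) o[i] = xp[i] > 0 ? xp[i] : 0.0; break;
    default: stop("unknown activation kind");
  }
  if (!Rf_isNull(x.attr("dim"))) out.attr("dim") = x.attr("dim");
  return out;
}

// dy * f'(x) in one pass, same kind codes as cpp_act_fwd.
// [[Rcpp::export]]
NumericVector cpp_act_bwd(NumericVector x, NumericVector dy, int kind) {
  const double lam = 1.0507009873554804934193349852946;
  const double lb = lam * 1.6732632423543772848170429916717;
  NumericVector out(x.size());
  const double* xp = REAL(x);
  const double* dp = REAL(dy);
  double* o = REAL(out);
  R_xlen_t n = x.size();
  switch (kind) {
    case 0:
      for (R_xlen_t i = 0; i < n; ++i) {
        double s = 1.0 / (1.0 + std::exp(-xp[i]));
        o[i] = dp[i] * (s + xp[i] * s * (1.0 - s));
      }
      break;
    case 1:
      for (R_xlen_t i = 0; i < n; ++i) {
        double s = 1.0 / (1.0 + std::exp(-xp[i]));
        o[i] = dp[i] * s * (1.0 - s);
      }
      break;
    case 2:
      for (R_xlen_t i = 0; i < n; ++i)
        o[i] = dp[i] * (xp[i] > 0 ? lam : lb * std::exp(xp[i]));
      break;
    case 3:
      for (R_xlen_t i = 0; i < n; ++i) o[i] = xp[i] > 0 ? dp[i] : 0.0;
      break;
    default: stop("unknown activation kind");
  }
  if (!Rf_isNull(x.attr("dim"))) out.attr("dim") = x.attr("dim");
  return out;
}

// SE gate forward: y = x * g[c, n] (gate broadcast over H, W).
// [[Rcpp::export]]
NumericVector cpp_gate_fwd(NumericVector x, NumericVector g) {
  IntegerVector xd = x.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector out(x.size());
  const double* xp = REAL(x);
  const double* gp = REAL(g);
  double* o = REAL(out);
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double gc = gp[c + (size_t)C * n];
      for (size_t j = 0; j < HW; ++j, ++i) o[i] = xp[i] * gc;
    }
  out.attr("dim") = xd;
  return out;
}

// SE gate backward: dx = dy * g[c,n]; dg[c,n] = sum_{h,w} dy * x.
// [[Rcpp::export]]
List cpp_gate_bwd(NumericVector x, NumericVector g, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector dx(x.size());
  NumericVector dg((R_xlen_t)C * N);
  const double* xp = REAL(x);
  const double* gp = REAL(g);
  const double* dp = REAL(dy);
  double* dxp = REAL(dx);
  double* dgp = REAL(dg);
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double gc = gp[c + (size_t)C * n];
      double s = 0.0;
      for (size_t j = 0; j < HW; ++j, ++i) {
        dxp[i] = dp[i] * gc;
        s += dp[i] * xp[i];
      }
      dgp[c + (size_t)C * n] = s;
    }
  dx.attr("dim") = xd;
  dg.attr("dim") = IntegerVector::create(1, 1, C, N);
  return List::create(_["dx"] = dx, _["dg"] = dg);
}

// GAP backward: broadcast dy[c,n] / (H*W) over spatial positions.
// [[Rcpp::export]]
NumericVector cpp_gap_bwd(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int C = yd[2], N = yd[3];
  size_t HW = (size_t)H * W;
  NumericVector dx((R_xlen_t)HW * C * N);
  const double* dp = REAL(dy);
  double* o = REAL(dx);
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double v = dp[c + (size_t)C * n] / (double)HW;
      for (size_t j = 0; j < HW; ++j, ++i) o[i] = v;
    }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
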