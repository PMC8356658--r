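// Low-level tensor kernels for the network engine.
//
// All activation volumes are R arrays with dim (H, W, C, N) in column-major
// order; weights for full convolutions have dim (kh, kw, Cin, Cout) and for
// depthwise convolutions (kh, kw, C).  Spatial "same" padding follows the
// ceil(H/stride) output-size convention (asymmetric zero padding when the
// total pad is odd, extra row/column at the bottom/right).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int s) { return (n + s - 1) / s; }
static inline int pad_beg(int n, int k, int s) {
  int total = (out_dim(n, s) - 1) * s + k - n;
  if (total < 0) total = 0;
  return total / 2;
}

// ---------------------------------------------------------------- full conv

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                         int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: weight Cin mismatch");
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const int ph = pad_beg(H, kh, stride), pw = pad_beg(W, kw, stride);
  const int K = kh * kw * Cin, P = Ho * Wo;
  const bool has_b = bias.size() > 0;

  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector y(P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  if (kh == 1 && kw == 1 && stride == 1) {
    // pointwise: pure GEMM on the (H*W) x Cin matrix view of each image
    for (int n = 0; n < N; ++n) {
      arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)P * Cin * n,
                   P, Cin, false, true);
      arma::mat Ym(y.begin() + (size_t)P * Cout * n, P, Cout, false, true);
      Ym = Xm * Wm;
      if (has_b)
        for (int o = 0; o < Cout; ++o) Ym.col(o) += bias[o];
    }
    return y;
  }

  arma::mat col(P, K);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    col.zeros();
    for (int c = 0; c < Cin; ++c) {
      const double* xc = xn + (size_t)H * W * c;
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const int kidx = i + kh * j + kh * kw * c;
          double* colk = col.colptr(kidx);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + j - pw;
            if (wi < 0 || wi >= W) continue;
            const double* xcw = xc + (size_t)H * wi;
            double* colw = colk + (size_t)Ho * wo;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + i - ph;
              if (hi < 0 || hi >= H) continue;
              colw[ho] = xcw[hi];
            }
          }
        }
      }
    }
    arma::mat Ym(y.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    Ym = col * Wm;
    if (has_b)
      for (int o = 0; o < Cout; ++o) Ym.col(o) += bias[o];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const int ph = pad_beg(H, kh, stride), pw = pad_beg(W, kw, stride);
  const int K = kh * kw * Cin, P = Ho * Wo;

  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  arma::mat dWm(dw.begin(), K, Cout, false, true);

  if (kh == 1 && kw == 1 && stride == 1) {
    for (int n = 0; n < N; ++n) {
      arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)P * Cin * n,
                   P, Cin, false, true);
      arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)P * Cout * n,
                    P, Cout, false, true);
      arma::mat dXm(dx.begin() + (size_t)P * Cin * n, P, Cin, false, true);
      dWm += Xm.t() * dYm;
      dXm = dYm * Wm.t();
      if (has_bias)
        for (int o = 0; o < Cout; ++o) db[o] += arma::accu(dYm.col(o));
    }
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }

  arma::mat col(P, K), dcol(P, K);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    // rebuild col (recompute instead of caching: memory-lean)
    col.zeros();
    for (int c = 0; c < Cin; ++c) {
      const double* xc = xn + (size_t)H * W * c;
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          const int kidx = i + kh * j + kh * kw * c;
          double* colk = col.colptr(kidx);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + j - pw;
            if (wi < 0 || wi >= W) continue;
            const double* xcw = xc + (size_t)H * wi;
            double* colw = colk + (size_t)Ho * wo;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + i - ph;
              if (hi < 0 || hi >= H) continue;
              colw[ho] = xcw[hi];
            }
          }
        }
    }
    arma::mat dYm(dy.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    dWm += col.t() * dYm;
    if (has_bias)
      for (int o = 0; o < Cout; ++o) db[o] += arma::accu(dYm.col(o));
    dcol = dYm * Wm.t();
    double* dxn = dx.begin() + (size_t)H * W * Cin * n;
    for (int c = 0; c < Cin; ++c) {
      double* dxc = dxn + (size_t)H * W * c;
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          const int kidx = i + kh * j + kh * kw * c;
          const double* dcolk = dcol.colptr(kidx);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + j - pw;
            if (wi < 0 || wi >= W) continue;
            double* dxcw = dxc + (size_t)H * wi;
            const double* dcolw = dcolk + (size_t)Ho * wo;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + i - ph;
              if (hi < 0 || hi >= H) continue;
              dxcw[hi] += dcolw[ho];
            }
          }
        }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ----------------------------------------------------------- depthwise conv

// [[Rcpp::export(name = ".dwconv2d_fwd")]]
NumericVector dwconv2d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                           int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv2d: channel mismatch");
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const int ph = pad_beg(H, kh, stride), pw = pad_beg(W, kw, stride);
  const bool has_b = bias.size() > 0;

  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const double b = has_b ? bias[c] : 0.0;
      if (kh == 3 && kw == 3 && stride == 1 && H >= 3 && W >= 3) {
        const double w00 = wc[0], w10 = wc[1], w20 = wc[2],
                     w01 = wc[3], w11 = wc[4], w21 = wc[5],
                     w02 = wc[6], w12 = wc[7], w22 = wc[8];
        for (int wo = 0; wo < Wo; ++wo) {
          const bool wedge = (wo == 0 || wo == W - 1);
          const double* x0 = xc + (size_t)H * (wo - 1);
          const double* x1 = xc + (size_t)H * wo;
          const double* x2 = xc + (size_t)H * (wo + 1);
          double* yp = yc + (size_t)Ho * wo;
          for (int ho = 1; !wedge && ho < Ho - 1; ++ho) {
            const double acc = b +
              w00 * x0[ho - 1] + w10 * x0[ho] + w20 * x0[ho + 1] +
              w01 * x1[ho - 1] + w11 * x1[ho] + w21 * x1[ho + 1] +
              w02 * x2[ho - 1] + w12 * x2[ho] + w22 * x2[ho + 1];
            yp[ho] = acc;
          }
          // borders (and whole edge columns) via the generic path
          for (int ho = 0; ho < Ho; ++ho) {
            if (!wedge && ho != 0 && ho != Ho - 1) continue;
            double acc = b;
            for (int j = 0; j < 3; ++j) {
              const int wi = wo + j - 1;
              if (wi < 0 || wi >= W) continue;
              for (int i = 0; i < 3; ++i) {
                const int hi = ho + i - 1;
                if (hi < 0 || hi >= H) continue;
                acc += wc[i + 3 * j] * xc[hi + (size_t)H * wi];
              }
            }
            yp[ho] = acc;
          }
        }
        continue;
      }
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = b;
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * stride + j - pw;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * stride + i - ph;
              if (hi < 0 || hi >= H) continue;
              acc += wc[i + kh * j] * xc[hi + (size_t)H * wi];
            }
          }
          yc[ho + (size_t)Ho * wo] = acc;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".dwconv2d_bwd")]]
List dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  const int ph = pad_beg(H, kh, stride), pw = pad_beg(W, kw, stride);

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? C : 0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = dw.begin() + (size_t)kh * kw * c;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = dyc[ho + (size_t)Ho * wo];
          if (g == 0.0) continue;
          if (has_bias) db[c] += g;
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * stride + j - pw;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * stride + i - ph;
              if (hi < 0 || hi >= H) continue;
              dwc[i + kh * j] += g * xc[hi + (size_t)H * wi];
              dxc[hi + (size_t)H * wi] += g * wc[i + kh * j];
            }
          }
        }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// -------------------------------------------------- dense 2x2 stride-1 max

// Edge-replicated ("clamped") 2x2 max with stride 1: output same size.
// argmax codes: 0 = (h,w), 1 = (h+1,w), 2 = (h,w+1), 3 = (h+1,w+1).

// [[Rcpp::export(name = ".maxpool2_s1_fwd")]]
List maxpool2_s1_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  IntegerVector arg(x.size());
  arg.attr("dim") = xd;
  for (int q = 0; q < C * N; ++q) {
    const double* xc = x.begin() + (size_t)H * W * q;
    double* yc = y.begin() + (size_t)H * W * q;
    int* ac = arg.begin() + (size_t)H * W * q;
    for (int w = 0; w < W; ++w) {
      const int w2 = (w + 1 < W) ? w + 1 : w;
      for (int h = 0; h < H; ++h) {
        const int h2 = (h + 1 < H) ? h + 1 : h;
        double best = xc[h + (size_t)H * w];
        int code = 0;
        double v = xc[h2 + (size_t)H * w];
        if (v > best) { best = v; code = 1; }
        v = xc[h + (size_t)H * w2];
        if (v > best) { best = v; code = 2; }
        v = xc[h2 + (size_t)H * w2];
        if (v > best) { best = v; code = 3; }
        yc[h + (size_t)H * w] = best;
        ac[h + (size_t)H * w] = code;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_s1_bwd")]]
NumericVector maxpool2_s1_bwd(NumericVector dy, IntegerVector arg) {
  IntegerVector xd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector dx(dy.size());
  dx.attr("dim") = xd;
  for (int q = 0; q < C * N; ++q) {
    const double* dyc = dy.begin() + (size_t)H * W * q;
    const int* ac = arg.begin() + (size_t)H * W * q;
    double* dxc = dx.begin() + (size_t)H * W * q;
    for (int w = 0; w < W; ++w) {
      const int w2 = (w + 1 < W) ? w + 1 : w;
      for (int h = 0; h < H; ++h) {
        const int h2 = (h + 1 < H) ? h + 1 : h;
        const int code = ac[h + (size_t)H * w];
        const int hh = (code == 1 || code == 3) ? h2 : h;
        const int ww = (code >= 2) ? w2 : w;
        dxc[hh + (size_t)H * ww] += dyc[h + (size_t)H * w];
      }
    }
  }
  return dx;
}

// --------------------------------------- blur (fixed kernel) + subsample 2

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// [[Rcpp::export(name = ".blurpool_fwd")]]
NumericVector blurpool_fwd(NumericVector x, NumericVector kern, int stride) {
  IntegerVector xd = x.attr("dim"), kd = kern.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kb = kd[0];
  const int c0 = (kb - 1) / 2;
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double* xc = x.begin() + (size_t)H * W * q;
    double* yc = y.begin() + (size_t)Ho * Wo * q;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = 0.0;
        for (int j = 0; j < kb; ++j) {
          const int wi = reflect_idx(wo * stride + j - c0, W);
          for (int i = 0; i < kb; ++i) {
            const int hi = reflect_idx(ho * stride + i - c0, H);
            acc += kern[i + kb * j] * xc[hi + (size_t)H * wi];
          }
        }
        yc[ho + (size_t)Ho * wo] = acc;
      }
  }
  return y;
}

// [[Rcpp::export(name = ".blurpool_bwd")]]
NumericVector blurpool_bwd(NumericVector dy, NumericVector kern,
                           IntegerVector in_dim, int stride) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  IntegerVector kd = kern.attr("dim");
  const int kb = kd[0];
  const int c0 = (kb - 1) / 2;
  const int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = in_dim;
  for (int q = 0; q < C * N; ++q) {
    const double* dyc = dy.begin() + (size_t)Ho * Wo * q;
    double* dxc = dx.begin() + (size_t)H * W * q;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dyc[ho + (size_t)Ho * wo];
        if (g == 0.0) continue;
        for (int j = 0; j < kb; ++j) {
          const int wi = reflect_idx(wo * stride + j - c0, W);
          for (int i = 0; i < kb; ++i) {
            const int hi = reflect_idx(ho * stride + i - c0, H);
            dxc[hi + (size_t)H * wi] += g * kern[i + kb * j];
          }
        }
      }
  }
  return dx;
}

// ------------------------------------------------- fused batch-norm + act

// y = act((x - mu) * istd * gamma + beta), per channel; act = ReLU6 or id
// [[Rcpp::export(name = ".bn_act_fwd")]]
NumericVector bn_act_fwd(NumericVector x, NumericVector gamma,
                         NumericVector beta, NumericVector mu,
                         NumericVector istd, bool relu6) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double sc = gamma[c] * istd[c];
      const double sh = beta[c] - mu[c] * sc;
      const double* xc = x.begin() + (size_t)HW * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)HW * (c + (size_t)C * n);
      if (relu6) {
        for (int p = 0; p < HW; ++p) {
          double v = xc[p] * sc + sh;
          yc[p] = v < 0 ? 0 : (v > 6 ? 6 : v);
        }
      } else {
        for (int p = 0; p < HW; ++p) yc[p] = xc[p] * sc + sh;
      }
    }
  return y;
}

// [[Rcpp::export(name = ".bn_act_bwd")]]
List bn_act_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector beta, NumericVector mu, NumericVector istd,
                bool relu6, bool train_stats) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const double m = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  // pass 1: accumulate dgamma (vs xhat) and dbeta of dz
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double sc = gamma[c] * istd[c];
      const double sh = beta[c] - mu[c] * sc;
      const double* xc = x.begin() + (size_t)HW * (c + (size_t)C * n);
      const double* dyc = dy.begin() + (size_t)HW * (c + (size_t)C * n);
      double dg = 0, db = 0;
      if (relu6) {
        for (int p = 0; p < HW; ++p) {
          const double z = xc[p] * sc + sh;
          if (z <= 0 || z >= 6) continue;
          const double g = dyc[p];
          db += g;
          dg += g * (xc[p] - mu[c]) * istd[c];
        }
      } else {
        for (int p = 0; p < HW; ++p) {
          const double g = dyc[p];
          db += g;
          dg += g * (xc[p] - mu[c]) * istd[c];
        }
      }
      dgamma[c] += dg;
      dbeta[c] += db;
    }
  // pass 2: dx
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double sc = gamma[c] * istd[c];
      const double sh = beta[c] - mu[c] * sc;
      const double gi = gamma[c] * istd[c];
      const double t1 = train_stats ? dbeta[c] / m : 0.0;
      const double t2 = train_stats ? dgamma[c] / m : 0.0;
      const double* xc = x.begin() + (size_t)HW * (c + (size_t)C * n);
      const double* dyc = dy.begin() + (size_t)HW * (c + (size_t)C * n);
      double* dxc = dx.begin() + (size_t)HW * (c + (size_t)C * n);
      if (relu6) {
        for (int p = 0; p < HW; ++p) {
          const double z = xc[p] * sc + sh;
          const double g = (z <= 0 || z >= 6) ? 0 : dyc[p];
          const double xhat = (xc[p] - mu[c]) * istd[c];
          dxc[p] = gi * (g - t1 - xhat * t2);
        }
      } else {
        for (int p = 0; p < HW; ++p) {
          const double xhat = (xc[p] - mu[c]) * istd[c];
          dxc[p] = gi * (dyc[p] - t1 - xhat * t2);
        }
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// per-channel mean and biased variance over (H, W, N)
// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector mu(C), vr(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)HW * (c + (size_t)C * n);
      double s = 0, s2 = 0;
      for (int p = 0; p < HW; ++p) { s += xc[p]; s2 += xc[p] * xc[p]; }
      mu[c] += s;
      vr[c] += s2;
    }
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    vr[c] = vr[c] / m - mu[c] * mu[c];
    if (vr[c] < 0) vr[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = vr);
}

// plain ReLU6 forward/backward (for layers without batch norm)
// [[Rcpp::export(name = ".relu6_fwd")]]
NumericVector relu6_fwd_cpp(NumericVector x) {
  NumericVector y = clone(x);
  for (double& v : y) { if (v < 0) v = 0; else if (v > 6) v = 6; }
  y.attr("dim") = x.attr("dim");
  return y;
}

// --------------------------------------------------- channel slice/concat

// [[Rcpp::export(name = ".channel_slice")]]
NumericVector channel_slice(NumericVector x, int from, int len) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)HW * len * N);
  y.attr("dim") = IntegerVector::create(xd[0], xd[1], len, N);
  for (int n = 0; n < N; ++n)
    std::copy(x.begin() + (size_t)HW * (from - 1 + (size_t)C * n),
              x.begin() + (size_t)HW * (from - 1 + len + (size_t)C * n),
              y.begin() + (size_t)HW * len * n);
  return y;
}

// [[Rcpp::export(name = ".channel_concat2")]]
NumericVector channel_concat2(NumericVector a, NumericVector b) {
  IntegerVector ad = a.attr("dim"), bd = b.attr("dim");
  const int HW = ad[0] * ad[1], Ca = ad[2], Cb = bd[2], N = ad[3];
  NumericVector y((size_t)HW * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(ad[0], ad[1], Ca + Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(a.begin() + (size_t)HW * Ca * n,
              a.begin() + (size_t)HW * Ca * (n + 1),
              y.begin() + (size_t)HW * (Ca + Cb) * n);
    std::copy(b.begin() + (size_t)HW * Cb * n,
              b.begin() + (size_t)HW * Cb * (n + 1),
              y.begin() + (size_t)HW * (Ca + Cb) * n + (size_t)HW * Ca);
  }
  return y;
}

// ------------------------------------------------ grouped attention helpers

// channel max/avg per group: desc channels [max_1, avg_1, ..., max_g, avg_g]
// [[Rcpp::export(name = ".group_channel_pool")]]
List group_channel_pool(NumericVector x, int g) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const int n_per = C / g;
  NumericVector desc((size_t)HW * 2 * g * N);
  desc.attr("dim") = IntegerVector::create(xd[0], xd[1], 2 * g, N);
  IntegerVector amax((size_t)HW * g * N);
  amax.attr("dim") = IntegerVector::create(xd[0], xd[1], g, N);
  for (int n = 0; n < N; ++n)
    for (int i = 0; i < g; ++i) {
      double* dmax = desc.begin() + (size_t)HW * (2 * i + (size_t)2 * g * n);
      double* davg = dmax + HW;
      int* am = amax.begin() + (size_t)HW * (i + (size_t)g * n);
      const double* x0 = x.begin() + (size_t)HW * (i * n_per + (size_t)C * n);
      for (int p = 0; p < HW; ++p) {
        dmax[p] = x0[p];
        davg[p] = x0[p];
        am[p] = 1;
      }
      for (int c = 1; c < n_per; ++c) {
        const double* xc = x0 + (size_t)HW * c;
        for (int p = 0; p < HW; ++p) {
          davg[p] += xc[p];
          if (xc[p] > dmax[p]) { dmax[p] = xc[p]; am[p] = c + 1; }
        }
      }
      for (int p = 0; p < HW; ++p) davg[p] /= n_per;
    }
  return List::create(_["desc"] = desc, _["amax"] = amax);
}

// scatter descriptor gradients back to channels: dmax to argmax channel,
// davg / n to all channels of the group; accumulates into dx
// [[Rcpp::export(name = ".group_pool_bwd")]]
NumericVector group_pool_bwd(NumericVector dx, NumericVector ddesc,
                             IntegerVector amax, int g) {
  IntegerVector xd = dx.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const int n_per = C / g;
  NumericVector out = clone(dx);
  out.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int i = 0; i < g; ++i) {
      const double* dmax = ddesc.begin() + (size_t)HW * (2 * i + (size_t)2 * g * n);
      const double* davg = dmax + HW;
      const int* am = amax.begin() + (size_t)HW * (i + (size_t)g * n);
      double* o0 = out.begin() + (size_t)HW * (i * n_per + (size_t)C * n);
      for (int c = 0; c < n_per; ++c) {
        double* oc = o0 + (size_t)HW * c;
        for (int p = 0; p < HW; ++p) {
          oc[p] += davg[p] / n_per;
          if (am[p] == c + 1) oc[p] += dmax[p];
        }
      }
    }
  return out;
}

// y = x * (1 + broadcast(m)); m has one channel per group
// [[Rcpp::export(name = ".group_gate_fwd")]]
NumericVector group_gate_fwd(NumericVector x, NumericVector m, int g) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const int n_per = C / g;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const int i = c / n_per;
      const double* mc = m.begin() + (size_t)HW * (i + (size_t)g * n);
      const double* xc = x.begin() + (size_t)HW * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)HW * (c + (size_t)C * n);
      for (int p = 0; p < HW; ++p) yc[p] = xc[p] * (1.0 + mc[p]);
    }
  return y;
}

// backward of the gate: dx = dy * (1 + broadcast(m)); dm = group-sum(dy * x)
// [[Rcpp::export(name = ".group_gate_bwd")]]
List group_gate_bwd(NumericVector x, NumericVector m, NumericVector dy,
                    int g) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const int n_per = C / g;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dm((size_t)HW * g * N);
  dm.attr("dim") = IntegerVector::create(xd[0], xd[1], g, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const int i = c / n_per;
      const double* mc = m.begin() + (size_t)HW * (i + (size_t)g * n);
      double* dmc = dm.begin() + (size_t)HW * (i + (size_t)g * n);
      const double* xc = x.begin() + (size_t)HW * (c + (size_t)C * n);
      const double* dyc = dy.begin() + (size_t)HW * (c + (size_t)C * n);
      double* dxc = dx.begin() + (size_t)HW * (c + (size_t)C * n);
      for (int p = 0; p < HW; ++p) {
        dxc[p] = dyc[p] * (1.0 + mc[p]);
        dmc[p] += dyc[p] * xc[p];
      }
    }
  return List::create(_["dx"] = dx, _["dm"] = dm);
}
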