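// Grouped 2-D convolution and max-pooling kernels for the CPRSCA-ResNet
// forward/backward passes. Tensors are R arrays with dim (C, H, W, N)
// (channel fastest, sample slowest); weights have dim (Cout, Cin/g, kh, kw).
// Three code paths: a direct channel-vectorized depthwise path (one filter
// per channel), a pure-GEMM path for 1x1 stride-1 convolutions, and a
// batch-wide im2col + BLAS GEMM path for everything else. Padding is
// zero "same"-style, explicit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// im2col over all samples: P has (cg*kh*kw) rows and (Ho*Wo*N) columns;
// row r encodes (ci, a, b) as ci + cg*(a + kh*b); column = ho + Ho*(wo + Wo*n).
static void im2col_all(const double* x, int C, int H, int W, int N,
                       int c0, int cg, int kh, int kw,
                       int sh, int sw, int ph, int pw,
                       int Ho, int Wo, arma::mat& P) {
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        double* cp = P.colptr(col);
        for (int b = 0; b < kw; ++b) {
          const int w = wo * sw - pw + b;
          for (int a = 0; a < kh; ++a) {
            const int h = ho * sh - ph + a;
            double* dst = cp + cg * (a + kh * b);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              const double* src = xn + (c0 + (size_t)C * (h + (size_t)H * w));
              for (int ci = 0; ci < cg; ++ci) dst[ci] = src[ci];
            } else {
              for (int ci = 0; ci < cg; ++ci) dst[ci] = 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im_all(const arma::mat& dP, double* dx, int C, int H, int W,
                       int N, int c0, int cg, int kh, int kw,
                       int sh, int sw, int ph, int pw, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    double* dxn = dx + (size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        const double* cp = dP.colptr(col);
        for (int b = 0; b < kw; ++b) {
          const int w = wo * sw - pw + b;
          if (w < 0 || w >= W) continue;
          for (int a = 0; a < kh; ++a) {
            const int h = ho * sh - ph + a;
            if (h < 0 || h >= H) continue;
            const double* src = cp + cg * (a + kh * b);
            double* dst = dxn + (c0 + (size_t)C * (h + (size_t)H * w));
            for (int ci = 0; ci < cg; ++ci) dst[ci] += src[ci];
          }
        }
      }
    }
  }
}

// Weight matrix for group g: (Kg x cg*kh*kw), column layout matching im2col.
static arma::mat weight_mat(const double* wts, int Cout, int cg,
                            int kh, int kw, int g, int Kg) {
  arma::mat Wm(Kg, cg * kh * kw);
  for (int b = 0; b < kw; ++b)
    for (int a = 0; a < kh; ++a)
      for (int ci = 0; ci < cg; ++ci) {
        const size_t widx = (size_t)Cout * (ci + (size_t)cg * (a + (size_t)kh * b));
        for (int o = 0; o < Kg; ++o)
          Wm(o, ci + cg * (a + kh * b)) = wts[g * Kg + o + widx];
      }
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             int sh, int sw, int ph, int pw, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Cout = wd[0], cg = wd[1], kh = wd[2], kw = wd[3];
  if (C != cg * groups)
    stop("conv2d: input channels (%d) != groups (%d) * per-group channels (%d)",
         C, groups, cg);
  if (Cout % groups != 0) stop("conv2d: output channels not divisible by groups");
  const int Kg = Cout / groups;
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");

  NumericVector out(((size_t)Cout) * Ho * Wo * N);
  out.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);

  // depthwise path: one filter per channel, vectorized over channels
  if (cg == 1 && Kg == 1) {
    for (int n = 0; n < N; ++n) {
      const double* xn = x.begin() + (size_t)n * C * H * W;
      double* on = out.begin() + (size_t)n * C * Ho * Wo;
      std::vector<double> acc(C);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          std::fill(acc.begin(), acc.end(), 0.0);
          for (int b = 0; b < kw; ++b) {
            const int wv = wo * sw - pw + b;
            if (wv < 0 || wv >= W) continue;
            for (int a = 0; a < kh; ++a) {
              const int h = ho * sh - ph + a;
              if (h < 0 || h >= H) continue;
              const double* src = xn + (size_t)C * (h + (size_t)H * wv);
              const double* wp = w.begin() + (size_t)C * (a + (size_t)kh * b);
              for (int c = 0; c < C; ++c) acc[c] += src[c] * wp[c];
            }
          }
          double* dst = on + (size_t)C * (ho + (size_t)Ho * wo);
          for (int c = 0; c < C; ++c) dst[c] = acc[c];
        }
    }
    return out;
  }

  // pure-GEMM path for 1x1 stride-1 unpadded ungrouped convolution
  if (kh == 1 && kw == 1 && sh == 1 && sw == 1 && ph == 0 && pw == 0 &&
      groups == 1) {
    arma::mat X(const_cast<double*>(x.begin()), C, (size_t)H * W * N, false, true);
    arma::mat Wm(const_cast<double*>(w.begin()), Cout, C, false, true);
    arma::mat O(out.begin(), Cout, (size_t)H * W * N, false, true);
    O = Wm * X;
    return out;
  }

  arma::mat P(cg * kh * kw, (size_t)Ho * Wo * N);
  for (int g = 0; g < groups; ++g) {
    im2col_all(x.begin(), C, H, W, N, g * cg, cg, kh, kw, sh, sw, ph, pw,
               Ho, Wo, P);
    arma::mat Wm = weight_mat(w.begin(), Cout, cg, kh, kw, g, Kg);
    arma::mat O = Wm * P;  // Kg x (Ho*Wo*N)
    for (int n = 0; n < N; ++n) {
      double* on = out.begin() + (size_t)n * Cout * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
          double* dst = on + (g * Kg + (size_t)Cout * (ho + (size_t)Ho * wo));
          for (int o = 0; o < Kg; ++o) dst[o] = O(o, col);
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                    int sh, int sw, int ph, int pw, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Cout = wd[0], cg = wd[1], kh = wd[2], kw = wd[3];
  const int Kg = Cout / groups;
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;

  if (cg == 1 && Kg == 1) {
    for (int n = 0; n < N; ++n) {
      const double* xn = x.begin() + (size_t)n * C * H * W;
      const double* dn = dout.begin() + (size_t)n * C * Ho * Wo;
      double* dxn = dx.begin() + (size_t)n * C * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double* dsrc = dn + (size_t)C * (ho + (size_t)Ho * wo);
          for (int b = 0; b < kw; ++b) {
            const int wv = wo * sw - pw + b;
            if (wv < 0 || wv >= W) continue;
            for (int a = 0; a < kh; ++a) {
              const int h = ho * sh - ph + a;
              if (h < 0 || h >= H) continue;
              const size_t xoff = (size_t)C * (h + (size_t)H * wv);
              const size_t woff = (size_t)C * (a + (size_t)kh * b);
              double* dxp = dxn + xoff;
              double* dwp = dw.begin() + woff;
              const double* xp = xn + xoff;
              const double* wp = w.begin() + woff;
              for (int c = 0; c < C; ++c) {
                dxp[c] += wp[c] * dsrc[c];
                dwp[c] += xp[c] * dsrc[c];
              }
            }
          }
        }
    }
    return List::create(_["dx"] = dx, _["dw"] = dw);
  }

  if (kh == 1 && kw == 1 && sh == 1 && sw == 1 && ph == 0 && pw == 0 &&
      groups == 1) {
    arma::mat X(const_cast<double*>(x.begin()), C, (size_t)H * W * N, false, true);
    arma::mat Wm(const_cast<double*>(w.begin()), Cout, C, false, true);
    arma::mat dO(const_cast<double*>(dout.begin()), Cout, (size_t)H * W * N, false, true);
    arma::mat dX(dx.begin(), C, (size_t)H * W * N, false, true);
    arma::mat dW(dw.begin(), Cout, C, false, true);
    dW = dO * X.t();
    dX = Wm.t() * dO;
    return List::create(_["dx"] = dx, _["dw"] = dw);
  }

  arma::mat P(cg * kh * kw, (size_t)Ho * Wo * N);
  arma::mat dO(Kg, (size_t)Ho * Wo * N);
  for (int g = 0; g < groups; ++g) {
    im2col_all(x.begin(), C, H, W, N, g * cg, cg, kh, kw, sh, sw, ph, pw,
               Ho, Wo, P);
    for (int n = 0; n < N; ++n) {
      const double* dn = dout.begin() + (size_t)n * Cout * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
          const double* src = dn + (g * Kg + (size_t)Cout * (ho + (size_t)Ho * wo));
          for (int o = 0; o < Kg; ++o) dO(o, col) = src[o];
        }
    }
    arma::mat Wm = weight_mat(w.begin(), Cout, cg, kh, kw, g, Kg);
    arma::mat dWm = dO * P.t();
    arma::mat dP = Wm.t() * dO;
    col2im_all(dP, dx.begin(), C, H, W, N, g * cg, cg, kh, kw, sh, sw,
               ph, pw, Ho, Wo);
    for (int b = 0; b < kw; ++b)
      for (int a = 0; a < kh; ++a)
        for (int ci = 0; ci < cg; ++ci) {
          const size_t widx = (size_t)Cout * (ci + (size_t)cg * (a + (size_t)kh * b));
          for (int o = 0; o < Kg; ++o)
            dw[g * Kg + o + widx] += dWm(o, ci + cg * (a + kh * b));
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Max pooling with -Inf padding; records flat argmax indices (1-based into
// the input array) so the backward pass is a scatter-add.
// [[Rcpp::export]]
List maxpool2d_fwd_cpp(NumericVector x, int kh, int kw,
                       int sh, int sw, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  if (Ho < 1 || Wo < 1) stop("maxpool: output size would be empty");

  NumericVector out(((size_t)C) * Ho * Wo * N);
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  NumericVector arg(out.size());  // double to hold large indices safely
  arg.attr("dim") = out.attr("dim");

  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          size_t best_idx = 0;
          for (int b = 0; b < kw; ++b) {
            const int wv = wo * sw - pw + b;
            if (wv < 0 || wv >= W) continue;
            for (int a = 0; a < kh; ++a) {
              const int hv = ho * sh - ph + a;
              if (hv < 0 || hv >= H) continue;
              const size_t idx = xoff + c + (size_t)C * (hv + (size_t)H * wv);
              if (x[idx] > best) { best = x[idx]; best_idx = idx; }
            }
          }
          const size_t oidx = (size_t)n * C * Ho * Wo + c +
            (size_t)C * (ho + (size_t)Ho * wo);
          out[oidx] = best;
          arg[oidx] = (double)(best_idx + 1);
        }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2d_bwd_cpp(NumericVector dout, NumericVector argmax,
                                IntegerVector in_dim) {
  NumericVector dx((size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    dx[(size_t)argmax[i] - 1] += dout[i];
  return dx;
}
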