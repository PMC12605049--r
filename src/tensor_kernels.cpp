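// Hot elementwise/normalization kernels for the training loop, operating
// on (C, H, W, N) tensors (channel fastest). These mirror the reference R
// implementations in tensor-ops.R / attention-ops.R and are checked
// against them (and against finite differences) in the test suite.

#include <Rcpp.h>
using namespace Rcpp;

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D tensor");
  return d;
}

// [[Rcpp::export]]
List groupnorm_fwd_cpp(NumericVector x, NumericVector gamma,
                       NumericVector beta, int G, double eps) {
  IntegerVector d = dims4(x);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  if (C % G != 0) stop("groupnorm: %d channels not divisible by %d groups", C, G);
  const int cg = C / G;
  const double m = (double)cg * H * W;

  NumericVector out(x.size()), xhat(x.size());
  out.attr("dim") = d; xhat.attr("dim") = d;
  NumericMatrix inv_sd(G, N);

  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * C * H * W;
    for (int g = 0; g < G; ++g) {
      const int c0 = g * cg;
      double s = 0, ss = 0;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double* p = x.begin() + off + c0 + (size_t)C * (h + (size_t)H * w);
          for (int c = 0; c < cg; ++c) { s += p[c]; ss += p[c] * p[c]; }
        }
      const double mu = s / m;
      const double var = ss / m - mu * mu;
      const double isd = 1.0 / std::sqrt(var + eps);
      inv_sd(g, n) = isd;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const size_t base = off + c0 + (size_t)C * (h + (size_t)H * w);
          const double* p = x.begin() + base;
          double* xh = xhat.begin() + base;
          double* o = out.begin() + base;
          for (int c = 0; c < cg; ++c) {
            xh[c] = (p[c] - mu) * isd;
            o[c] = gamma[c0 + c] * xh[c] + beta[c0 + c];
          }
        }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
List groupnorm_bwd_cpp(NumericVector xhat, NumericMatrix inv_sd,
                       NumericVector gamma, NumericVector dout, int G) {
  IntegerVector d = dims4(xhat);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  const int cg = C / G;
  const double m = (double)cg * H * W;

  NumericVector dx(xhat.size());
  dx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);

  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * C * H * W;
    for (int g = 0; g < G; ++g) {
      const int c0 = g * cg;
      double s1 = 0, s2 = 0;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const size_t base = off + c0 + (size_t)C * (h + (size_t)H * w);
          const double* dj = dout.begin() + base;
          const double* xh = xhat.begin() + base;
          for (int c = 0; c < cg; ++c) {
            const double dxh = dj[c] * gamma[c0 + c];
            s1 += dxh;
            s2 += dxh * xh[c];
            dgamma[c0 + c] += dj[c] * xh[c];
            dbeta[c0 + c] += dj[c];
          }
        }
      const double isd = inv_sd(g, n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const size_t base = off + c0 + (size_t)C * (h + (size_t)H * w);
          const double* dj = dout.begin() + base;
          const double* xh = xhat.begin() + base;
          double* dxp = dx.begin() + base;
          for (int c = 0; c < cg; ++c) {
            const double dxh = dj[c] * gamma[c0 + c];
            dxp[c] = isd * (dxh - s1 / m - xh[c] * s2 / m);
          }
        }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// softmax over channels with per-position max subtraction
// [[Rcpp::export]]
NumericVector softmax_channels_cpp(NumericVector x) {
  IntegerVector d = dims4(x);
  const int C = d[0];
  const size_t K = (size_t)d[1] * d[2] * d[3];
  NumericVector out(x.size());
  out.attr("dim") = d;
  for (size_t k = 0; k < K; ++k) {
    const double* p = x.begin() + k * C;
    double* o = out.begin() + k * C;
    double mx = p[0];
    for (int c = 1; c < C; ++c) if (p[c] > mx) mx = p[c];
    double s = 0;
    for (int c = 0; c < C; ++c) { o[c] = std::exp(p[c] - mx); s += o[c]; }
    for (int c = 0; c < C; ++c) o[c] /= s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector softmax_channels_bwd_cpp(NumericVector s, NumericVector dy) {
  IntegerVector d = dims4(s);
  const int C = d[0];
  const size_t K = (size_t)d[1] * d[2] * d[3];
  NumericVector dx(s.size());
  dx.attr("dim") = d;
  for (size_t k = 0; k < K; ++k) {
    const double* sp = s.begin() + k * C;
    const double* dp = dy.begin() + k * C;
    double* o = dx.begin() + k * C;
    double dot = 0;
    for (int c = 0; c < C; ++c) dot += sp[c] * dp[c];
    for (int c = 0; c < C; ++c) o[c] = sp[c] * (dp[c] - dot);
  }
  return dx;
}

// directional means: zh (C,H,N) over width, zw (C,W,N) over height
// [[Rcpp::export]]
List directional_means_cpp(NumericVector x) {
  IntegerVector d = dims4(x);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  NumericVector zh((size_t)C * H * N), zw((size_t)C * W * N);
  zh.attr("dim") = IntegerVector::create(C, H, N);
  zw.attr("dim") = IntegerVector::create(C, W, N);
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * C * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double* p = x.begin() + off + (size_t)C * (h + (size_t)H * w);
        double* ph = zh.begin() + (size_t)n * C * H + (size_t)C * h;
        double* pw = zw.begin() + (size_t)n * C * W + (size_t)C * w;
        for (int c = 0; c < C; ++c) { ph[c] += p[c]; pw[c] += p[c]; }
      }
  }
  for (R_xlen_t i = 0; i < zh.size(); ++i) zh[i] /= W;
  for (R_xlen_t i = 0; i < zw.size(); ++i) zw[i] /= H;
  return List::create(_["zh"] = zh, _["zw"] = zw);
}

// backward of directional means: dzh/W broadcast + dzw/H broadcast
// [[Rcpp::export]]
NumericVector directional_means_bwd_cpp(NumericVector dzh, NumericVector dzw) {
  IntegerVector dh = dzh.attr("dim"), dw = dzw.attr("dim");
  const int C = dh[0], H = dh[1], N = dh[2], W = dw[1];
  NumericVector dx((size_t)C * H * W * N);
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * C * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double* o = dx.begin() + off + (size_t)C * (h + (size_t)H * w);
        const double* ph = dzh.begin() + (size_t)n * C * H + (size_t)C * h;
        const double* pw = dzw.begin() + (size_t)n * C * W + (size_t)C * w;
        for (int c = 0; c < C; ++c) o[c] = ph[c] / W + pw[c] / H;
      }
  }
  return dx;
}

// out[c,h,w,n] = x[c,h,w,n] * gh[c,h,n] * gw[c,w,n]
// [[Rcpp::export]]
NumericVector ca_modulate_fwd_cpp(NumericVector x, NumericVector gh,
                                  NumericVector gw) {
  IntegerVector d = dims4(x);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  NumericVector out(x.size());
  out.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * C * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double* p = x.begin() + off + (size_t)C * (h + (size_t)H * w);
        double* o = out.begin() + off + (size_t)C * (h + (size_t)H * w);
        const double* ph = gh.begin() + (size_t)n * C * H + (size_t)C * h;
        const double* pw = gw.begin() + (size_t)n * C * W + (size_t)C * w;
        for (int c = 0; c < C; ++c) o[c] = p[c] * ph[c] * pw[c];
      }
  }
  return out;
}

// [[Rcpp::export]]
List ca_modulate_bwd_cpp(NumericVector x, NumericVector gh, NumericVector gw,
                         NumericVector dout) {
  IntegerVector d = dims4(x);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  NumericVector dgh((size_t)C * H * N), dgw((size_t)C * W * N);
  dgh.attr("dim") = IntegerVector::create(C, H, N);
  dgw.attr("dim") = IntegerVector::create(C, W, N);
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * C * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const size_t base = off + (size_t)C * (h + (size_t)H * w);
        const double* p = x.begin() + base;
        const double* dj = dout.begin() + base;
        const double* ph = gh.begin() + (size_t)n * C * H + (size_t)C * h;
        const double* pw = gw.begin() + (size_t)n * C * W + (size_t)C * w;
        double* oh = dgh.begin() + (size_t)n * C * H + (size_t)C * h;
        double* ow = dgw.begin() + (size_t)n * C * W + (size_t)C * w;
        double* od = dx.begin() + base;
        for (int c = 0; c < C; ++c) {
          od[c] = dj[c] * ph[c] * pw[c];
          oh[c] += dj[c] * p[c] * pw[c];
          ow[c] += dj[c] * p[c] * ph[c];
        }
      }
  }
  return List::create(_["dx"] = dx, _["dgh"] = dgh, _["dgw"] = dgw);
}

// channel-wise scaling: out[c,h,w,n] = a[c,h,w,n] * s[c,n]
// [[Rcpp::export]]
NumericVector channel_scale_fwd_cpp(NumericVector a, NumericVector s) {
  IntegerVector d = dims4(a);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  NumericVector out(a.size());
  out.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    const double* sp = s.begin() + (size_t)n * C;
    const size_t off = (size_t)n * C * H * W;
    for (size_t k = 0; k < (size_t)H * W; ++k) {
      const double* p = a.begin() + off + k * C;
      double* o = out.begin() + off + k * C;
      for (int c = 0; c < C; ++c) o[c] = p[c] * sp[c];
    }
  }
  return out;
}

// [[Rcpp::export]]
List channel_scale_bwd_cpp(NumericVector a, NumericVector s,
                           NumericVector dout) {
  IntegerVector d = dims4(a);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  NumericVector da(a.size());
  da.attr("dim") = d;
  NumericMatrix ds(C, N);
  for (int n = 0; n < N; ++n) {
    const double* sp = s.begin() + (size_t)n * C;
    const size_t off = (size_t)n * C * H * W;
    double* dsp = ds.begin() + (size_t)n * C;
    for (size_t k = 0; k < (size_t)H * W; ++k) {
      const double* p = a.begin() + off + k * C;
      const double* dj = dout.begin() + off + k * C;
      double* o = da.begin() + off + k * C;
      for (int c = 0; c < C; ++c) {
        o[c] = dj[c] * sp[c];
        dsp[c] += dj[c] * p[c];
      }
    }
  }
  return List::create(_["da"] = da, _["ds"] = ds);
}

// per-channel-per-sample spatial mean: (C,H,W,N) -> (C,N)
// [[Rcpp::export]]
NumericMatrix spatial_mean_cpp(NumericVector x) {
  IntegerVector d = dims4(x);
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  NumericMatrix z(C, N);
  for (int n = 0; n < N; ++n) {
    const size_t off = (size_t)n * C * H * W;
    double* zp = z.begin() + (size_t)n * C;
    for (size_t k = 0; k < (size_t)H * W; ++k) {
      const double* p = x.begin() + off + k * C;
      for (int c = 0; c < C; ++c) zp[c] += p[c];
    }
  }
  const double m = (double)H * W;
  for (R_xlen_t i = 0; i < z.size(); ++i) z[i] /= m;
  return z;
}

// broadcast (C,N) over (H,W), scaled: out[c,h,w,n] = s[c,n] * scale
// [[Rcpp::export]]
NumericVector channel_broadcast_cpp(NumericMatrix s, int H, int W,
                                    double scale) {
  const int C = s.nrow(), N = s.ncol();
  NumericVector out((size_t)C * H * W * N);
  out.attr("dim") = IntegerVector::create(C, H, W, N);
  for (int n = 0; n < N; ++n) {
    const double* sp = s.begin() + (size_t)n * C;
    const size_t off = (size_t)n * C * H * W;
    for (size_t k = 0; k < (size_t)H * W; ++k) {
      double* o = out.begin() + off + k * C;
      for (int c = 0; c < C; ++c) o[c] = sp[c] * scale;
    }
  }
  return out;
}
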