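#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensor layout throughout: R arrays with dim c(H, W, C, N), column-major,
// so the height index varies fastest. Kernels: dim c(kh, kw, Cin, Cout) for
// dense convolutions, c(kh, kw, C, M) for depthwise (channel multiplier M,
// output channel c*M + m derives from input channel c).
// All loops are single-threaded; determinism of the training loop relies on
// it.

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix (kh*kw*Cin x Ho*Wo) for sample n of x.
static void im2col(const double* xn, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride - pad + j;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hsrc = ho * stride - pad + i;
            if (hsrc < 0 || hsrc >= H) continue;
            col(r, ho + (size_t)Ho * wo) = xn[hsrc + (size_t)H * (wsrc + (size_t)W * c)];
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add columns back into the input gradient.
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* gxn) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride - pad + j;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hsrc = ho * stride - pad + i;
            if (hsrc < 0 || hsrc >= H) continue;
            gxn[hsrc + (size_t)H * (wsrc + (size_t)W * c)] += col(r, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                             int stride, int pad, bool use_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C)
    stop("channel mismatch: input has %d channels, kernel expects %d", C, Cin);
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("input smaller than kernel after padding");

  arma::mat wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat out = col.t() * wm;  // (Ho*Wo x Cout)
    if (use_bias) {
      arma::rowvec bv(const_cast<double*>(bias.begin()), Cout, false, true);
      out.each_row() += bv;
    }
    std::copy(out.begin(), out.end(), y.begin() + (size_t)Ho * Wo * Cout * n);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, bool use_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];

  arma::mat wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  arma::mat gw((size_t)kh * kw * Cin, Cout, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);
  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    arma::mat gyn(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * Cout * n,
                  (size_t)Ho * Wo, Cout, false, true);
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    gw += col * gyn;
    if (use_bias) gb += arma::sum(gyn, 0);
    arma::mat gcol = wm * gyn.t();  // (kh*kw*Cin x Ho*Wo)
    col2im(gcol, H, W, C, kh, kw, stride, pad, Ho, Wo, gx.begin() + (size_t)H * W * C * n);
  }

  NumericVector gwv(w.size());
  gwv.attr("dim") = wd;
  std::copy(gw.begin(), gw.end(), gwv.begin());
  NumericVector gbv(Cout);
  std::copy(gb.begin(), gb.end(), gbv.begin());
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// Depthwise convolution: each input channel c yields M output channels
// c*M + m, each from its own kh x kw kernel w[,,c,m].
// [[Rcpp::export]]
NumericVector dwconv2d_fwd_cpp(NumericVector x, NumericVector w, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cw = wd[2], M = wd[3];
  if (Cw != C)
    stop("channel mismatch: input has %d channels, depthwise kernel expects %d", C, Cw);
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);

  NumericVector y((size_t)Ho * Wo * C * M * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C * M, N);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* yn = y.begin() + (size_t)Ho * Wo * C * M * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (size_t)H * W * c;
      for (int m = 0; m < M; ++m) {
        const double* k = w.begin() + (size_t)kh * kw * (c + (size_t)C * m);
        double* yc = yn + (size_t)Ho * Wo * (c * M + m);
        for (int wo = 0; wo < Wo; ++wo) {
          for (int ho = 0; ho < Ho; ++ho) {
            double acc = 0.0;
            for (int j = 0; j < kw; ++j) {
              const int wsrc = wo * stride - pad + j;
              if (wsrc < 0 || wsrc >= W) continue;
              for (int i = 0; i < kh; ++i) {
                const int hsrc = ho * stride - pad + i;
                if (hsrc < 0 || hsrc >= H) continue;
                acc += k[i + kh * j] * xc[hsrc + (size_t)H * wsrc];
              }
            }
            yc[ho + (size_t)Ho * wo] = acc;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                      int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], M = wd[3];
  const int Ho = gd[0], Wo = gd[1];

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* gxn = gx.begin() + (size_t)H * W * C * n;
    const double* gyn = gy.begin() + (size_t)Ho * Wo * C * M * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (size_t)H * W * c;
      double* gxc = gxn + (size_t)H * W * c;
      for (int m = 0; m < M; ++m) {
        const double* k = w.begin() + (size_t)kh * kw * (c + (size_t)C * m);
        double* gk = gw.begin() + (size_t)kh * kw * (c + (size_t)C * m);
        const double* gyc = gyn + (size_t)Ho * Wo * (c * M + m);
        for (int wo = 0; wo < Wo; ++wo) {
          for (int ho = 0; ho < Ho; ++ho) {
            const double g = gyc[ho + (size_t)Ho * wo];
            if (g == 0.0) continue;
            for (int j = 0; j < kw; ++j) {
              const int wsrc = wo * stride - pad + j;
              if (wsrc < 0 || wsrc >= W) continue;
              for (int i = 0; i < kh; ++i) {
                const int hsrc = ho * stride - pad + i;
                if (hsrc < 0 || hsrc >= H) continue;
                gk[i + kh * j] += g * xc[hsrc + (size_t)H * wsrc];
                gxc[hsrc + (size_t)H * wsrc] += g * k[i + kh * j];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}
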