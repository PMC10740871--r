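// Low-level 3D convolution kernels for the spatiotemporal encoder-decoder.
//
// Tensor layout: a clip activation is a dense double array with dims
// (C, T, H, W, N), column-major (channel fastest). Convolution weights are
// stored as a (C*kt*kh*kw) x K matrix whose row index is
// c + C*(dt + kt*(dh + kh*dw)); this makes forward a single GEMM per
// column block against the vol2col patch matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword idx4(int c, int t, int h, int w,
                               int C, int T, int H) {
  return (arma::uword)c + (arma::uword)C * ((arma::uword)t +
         (arma::uword)T * ((arma::uword)h + (arma::uword)H * (arma::uword)w));
}

// Fill `col` (CkV x nb) with patches for output positions [p0, p0+nb).
// Output positions are ordered to-fastest: p = to + To*(ho + Ho*wo).
static void vol2col_block(const double* x, int C, int T, int H, int W,
                          int kt, int kh, int kw,
                          int pt, int ph, int pw,
                          int To, int Ho,
                          arma::uword p0, arma::uword nb, arma::mat& col) {
  const int CkV = C * kt * kh * kw;
  for (arma::uword j = 0; j < nb; ++j) {
    arma::uword p = p0 + j;
    int to = (int)(p % (arma::uword)To);
    int rem = (int)(p / (arma::uword)To);
    int ho = rem % Ho;
    int wo = rem / Ho;
    double* dst = col.colptr(j);
    int r = 0;
    for (int dw = 0; dw < kw; ++dw) {
      int wi = wo - pw + dw;
      for (int dh = 0; dh < kh; ++dh) {
        int hi = ho - ph + dh;
        for (int dt = 0; dt < kt; ++dt) {
          int ti = to - pt + dt;
          if (wi < 0 || wi >= W || hi < 0 || hi >= H || ti < 0 || ti >= T) {
            for (int c = 0; c < C; ++c) dst[((dt + kt*(dh + kh*dw)))*C + c] = 0.0;
          } else {
            const double* src = x + idx4(0, ti, hi, wi, C, T, H);
            double* d2 = dst + (dt + kt*(dh + kh*dw))*C;
            for (int c = 0; c < C; ++c) d2[c] = src[c];
          }
        }
      }
    }
    (void)r; (void)CkV;
  }
}

// Scatter-add a gcol block back into gx (reverse of vol2col_block).
static void col2vol_block(const arma::mat& gcol, double* gx,
                          int C, int T, int H, int W,
                          int kt, int kh, int kw,
                          int pt, int ph, int pw,
                          int To, int Ho,
                          arma::uword p0, arma::uword nb) {
  for (arma::uword j = 0; j < nb; ++j) {
    arma::uword p = p0 + j;
    int to = (int)(p % (arma::uword)To);
    int rem = (int)(p / (arma::uword)To);
    int ho = rem % Ho;
    int wo = rem / Ho;
    const double* src = gcol.colptr(j);
    for (int dw = 0; dw < kw; ++dw) {
      int wi = wo - pw + dw;
      if (wi < 0 || wi >= W) continue;
      for (int dh = 0; dh < kh; ++dh) {
        int hi = ho - ph + dh;
        if (hi < 0 || hi >= H) continue;
        for (int dt = 0; dt < kt; ++dt) {
          int ti = to - pt + dt;
          if (ti < 0 || ti >= T) continue;
          double* dst = gx + idx4(0, ti, hi, wi, C, T, H);
          const double* s2 = src + (dt + kt*(dh + kh*dw))*C;
          for (int c = 0; c < C; ++c) dst[c] += s2[c];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericMatrix wmat, NumericVector bias,
                             IntegerVector kdim, IntegerVector pad) {
  const int C = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int kt = kdim[0], kh = kdim[1], kw = kdim[2];
  const int pt = pad[0],  ph = pad[1],  pw = pad[2];
  const int To = T + 2*pt - kt + 1;
  const int Ho = H + 2*ph - kh + 1;
  const int Wo = W + 2*pw - kw + 1;
  if (To < 1 || Ho < 1 || Wo < 1)
    stop("convolution output would be empty (input smaller than kernel)");
  const int K = wmat.ncol();
  const int CkV = C * kt * kh * kw;
  if (wmat.nrow() != CkV) stop("weight matrix rows do not match C*kt*kh*kw");

  const arma::uword P = (arma::uword)To * Ho * Wo;
  const arma::uword sampIn  = (arma::uword)C * T * H * W;
  const arma::uword sampOut = (arma::uword)K * P;
  NumericVector y((R_xlen_t)(sampOut * (arma::uword)N));
  arma::mat Wm(wmat.begin(), CkV, K, false, true);
  arma::vec bv(bias.begin(), K, false, true);

  const arma::uword blk = std::max<arma::uword>(1, std::min<arma::uword>(P, (arma::uword)(1 << 15)));
  arma::mat col(CkV, blk);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (arma::uword)n * sampIn;
    double* ys = y.begin() + (arma::uword)n * sampOut;
    for (arma::uword p0 = 0; p0 < P; p0 += blk) {
      arma::uword nb = std::min<arma::uword>(blk, P - p0);
      vol2col_block(xs, C, T, H, W, kt, kh, kw, pt, ph, pw, To, Ho, p0, nb, col);
      arma::mat yb(ys + (arma::uword)K * p0, K, nb, false, true);
      yb = Wm.t() * col.cols(0, nb - 1);
      yb.each_col() += bv;
    }
  }
  y.attr("dim") = IntegerVector::create(K, To, Ho, Wo, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim,
                    NumericMatrix wmat, NumericVector gy,
                    IntegerVector kdim, IntegerVector pad) {
  const int C = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int kt = kdim[0], kh = kdim[1], kw = kdim[2];
  const int pt = pad[0],  ph = pad[1],  pw = pad[2];
  const int To = T + 2*pt - kt + 1;
  const int Ho = H + 2*ph - kh + 1;
  const int Wo = W + 2*pw - kw + 1;
  const int K = wmat.ncol();
  const int CkV = C * kt * kh * kw;

  const arma::uword P = (arma::uword)To * Ho * Wo;
  const arma::uword sampIn  = (arma::uword)C * T * H * W;
  const arma::uword sampOut = (arma::uword)K * P;

  NumericVector gx((R_xlen_t)(sampIn * (arma::uword)N));
  arma::mat Wm(wmat.begin(), CkV, K, false, true);
  arma::mat gW(CkV, K, arma::fill::zeros);
  arma::vec gB(K, arma::fill::zeros);

  const arma::uword blk = std::max<arma::uword>(1, std::min<arma::uword>(P, (arma::uword)(1 << 15)));
  arma::mat col(CkV, blk);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (arma::uword)n * sampIn;
    double* gxs = gx.begin() + (arma::uword)n * sampIn;
    const double* gys = gy.begin() + (arma::uword)n * sampOut;
    for (arma::uword p0 = 0; p0 < P; p0 += blk) {
      arma::uword nb = std::min<arma::uword>(blk, P - p0);
      vol2col_block(xs, C, T, H, W, kt, kh, kw, pt, ph, pw, To, Ho, p0, nb, col);
      arma::mat gyb(const_cast<double*>(gys) + (arma::uword)K * p0, K, nb, false, true);
      gW += col.cols(0, nb - 1) * gyb.t();
      gB += arma::sum(gyb, 1);
      arma::mat gcol = Wm * gyb;
      col2vol_block(gcol, gxs, C, T, H, W, kt, kh, kw, pt, ph, pw, To, Ho, p0, nb);
    }
  }
  gx.attr("dim") = IntegerVector::create(C, T, H, W, N);
  return List::create(_["gx"] = gx,
                      _["gw"] = wrap(gW),
                      _["gb"] = wrap(gB));
}

// Average pooling, stride equal to the kernel, exact division assumed
// (validated at the R level).
// [[Rcpp::export]]
NumericVector cpp_avgpool3d_fwd(NumericVector x, IntegerVector xdim,
                                IntegerVector kdim) {
  const int C = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int kt = kdim[0], kh = kdim[1], kw = kdim[2];
  const int To = T / kt, Ho = H / kh, Wo = W / kw;
  const double inv = 1.0 / (kt * kh * kw);
  const arma::uword sampIn = (arma::uword)C * T * H * W;
  const arma::uword sampOut = (arma::uword)C * To * Ho * Wo;
  NumericVector y((R_xlen_t)(sampOut * (arma::uword)N));
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (arma::uword)n * sampIn;
    double* ys = y.begin() + (arma::uword)n * sampOut;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int to = 0; to < To; ++to) {
          double* dst = ys + idx4(0, to, ho, wo, C, To, Ho);
          for (int c = 0; c < C; ++c) dst[c] = 0.0;
          for (int dw = 0; dw < kw; ++dw)
            for (int dh = 0; dh < kh; ++dh)
              for (int dt = 0; dt < kt; ++dt) {
                const double* src = xs + idx4(0, to*kt + dt, ho*kh + dh,
                                              wo*kw + dw, C, T, H);
                for (int c = 0; c < C; ++c) dst[c] += src[c];
              }
          for (int c = 0; c < C; ++c) dst[c] *= inv;
        }
  }
  y.attr("dim") = IntegerVector::create(C, To, Ho, Wo, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool3d_bwd(NumericVector gy, IntegerVector xdim,
                                IntegerVector kdim) {
  const int C = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int kt = kdim[0], kh = kdim[1], kw = kdim[2];
  const int To = T / kt, Ho = H / kh, Wo = W / kw;
  const double inv = 1.0 / (kt * kh * kw);
  const arma::uword sampIn = (arma::uword)C * T * H * W;
  const arma::uword sampOut = (arma::uword)C * To * Ho * Wo;
  NumericVector gx((R_xlen_t)(sampIn * (arma::uword)N));
  for (int n = 0; n < N; ++n) {
    const double* gys = gy.begin() + (arma::uword)n * sampOut;
    double* gxs = gx.begin() + (arma::uword)n * sampIn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int to = 0; to < To; ++to) {
          const double* src = gys + idx4(0, to, ho, wo, C, To, Ho);
          for (int dw = 0; dw < kw; ++dw)
            for (int dh = 0; dh < kh; ++dh)
              for (int dt = 0; dt < kt; ++dt) {
                double* dst = gxs + idx4(0, to*kt + dt, ho*kh + dh,
                                         wo*kw + dw, C, T, H);
                for (int c = 0; c < C; ++c) dst[c] += src[c] * inv;
              }
        }
  }
  gx.attr("dim") = IntegerVector::create(C, T, H, W, N);
  return gx;
}

// Temporal transposed convolution (kernel (kt,1,1), stride (s,1,1),
// temporal padding p): the decoder upsampler. Weights: (Cin*kt) x K matrix,
// row index c + Cin*j.
// [[Rcpp::export]]
NumericVector cpp_tdeconv_fwd(NumericVector x, IntegerVector xdim,
                              NumericMatrix wmat, NumericVector bias,
                              int kt, int stride, int pad) {
  const int C = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int K = wmat.ncol();
  const int To = (T - 1) * stride - 2 * pad + kt;
  const arma::uword sampIn = (arma::uword)C * T * H * W;
  const arma::uword sampOut = (arma::uword)K * To * H * W;
  NumericVector y((R_xlen_t)(sampOut * (arma::uword)N));
  // init with bias
  for (int n = 0; n < N; ++n) {
    double* ys = y.begin() + (arma::uword)n * sampOut;
    for (arma::uword q = 0; q < (arma::uword)To * H * W; ++q)
      for (int k = 0; k < K; ++k) ys[q * K + k] = bias[k];
  }
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (arma::uword)n * sampIn;
    double* ys = y.begin() + (arma::uword)n * sampOut;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int ti = 0; ti < T; ++ti) {
          const double* src = xs + idx4(0, ti, h, w, C, T, H);
          for (int j = 0; j < kt; ++j) {
            int to = ti * stride + j - pad;
            if (to < 0 || to >= To) continue;
            double* dst = ys + idx4(0, to, h, w, K, To, H);
            const double* wj = &wmat(C * j, 0);
            for (int k = 0; k < K; ++k) {
              const double* wc = wj + (arma::uword)k * (C * kt);
              double acc = 0.0;
              for (int c = 0; c < C; ++c) acc += wc[c] * src[c];
              dst[k] += acc;
            }
          }
        }
  }
  y.attr("dim") = IntegerVector::create(K, To, H, W, N);
  return y;
}

// [[Rcpp::export]]
List cpp_tdeconv_bwd(NumericVector x, IntegerVector xdim,
                     NumericMatrix wmat, NumericVector gy,
                     int kt, int stride, int pad) {
  const int C = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int K = wmat.ncol();
  const int To = (T - 1) * stride - 2 * pad + kt;
  const arma::uword sampIn = (arma::uword)C * T * H * W;
  const arma::uword sampOut = (arma::uword)K * To * H * W;
  NumericVector gx((R_xlen_t)(sampIn * (arma::uword)N));
  arma::mat gW(C * kt, K, arma::fill::zeros);
  arma::vec gB(K, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (arma::uword)n * sampIn;
    double* gxs = gx.begin() + (arma::uword)n * sampIn;
    const double* gys = gy.begin() + (arma::uword)n * sampOut;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int ti = 0; ti < T; ++ti) {
          const double* src = xs + idx4(0, ti, h, w, C, T, H);
          double* gsrc = gxs + idx4(0, ti, h, w, C, T, H);
          for (int j = 0; j < kt; ++j) {
            int to = ti * stride + j - pad;
            if (to < 0 || to >= To) continue;
            const double* g = gys + idx4(0, to, h, w, K, To, H);
            for (int k = 0; k < K; ++k) {
              const double gk = g[k];
              double* gwc = gW.colptr(k) + C * j;
              const double* wc = wmat.begin() + (arma::uword)k * (C * kt) + C * j;
              for (int c = 0; c < C; ++c) {
                gwc[c] += gk * src[c];
                gsrc[c] += gk * wc[c];
              }
            }
          }
        }
    // bias gradient: sum of gy over all positions
    for (arma::uword q = 0; q < (arma::uword)To * H * W; ++q)
      for (int k = 0; k < K; ++k) gB[k] += gys[q * K + k];
  }
  gx.attr("dim") = IntegerVector::create(C, T, H, W, N);
  return List::create(_["gx"] = gx, _["gw"] = wrap(gW), _["gb"] = wrap(gB));
}
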