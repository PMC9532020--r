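// Minimal grouped-2D-convolution / max-pooling kernels for the CNN.
// Arrays are R column-major with dims (H, W, C, N): H = frequency axis,
// W = time axis, C = channels (feature maps), N = batch. Convolutions are
// "valid" (no padding) cross-correlations, computed per channel group as
// im2col + BLAS matrix multiply. Weight matrices have one column per output
// channel; rows enumerate (kh, kw, in-channel-within-group) patch elements
// with kh fastest, matching the im2col fill below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_group(const double* xc, int H, int W, int cin_g,
                         int kh, int kw, int Ho, int Wo, arma::mat& Kt) {
  // xc points at the first channel of the group; channels are contiguous
  // blocks of H*W. Kt is (Ho*Wo) x (kh*kw*cin_g); column r holds patch
  // element (i, j, cc) across all output positions, ho fastest.
  for (int cc = 0; cc < cin_g; ++cc) {
    const double* ch = xc + (std::size_t)cc * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = cc * kh * kw + j * kh + i;
        double* dst = Kt.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const double* src = ch + (std::size_t)(j + wo) * H + i;
          std::memcpy(dst + (std::size_t)wo * Ho, src, sizeof(double) * Ho);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix w,
                             NumericVector b, int kh, int kw, int groups) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int cin_g = C / groups;
  int cout = w.ncol();
  int cout_g = cout / groups;
  int Ho = H - kh + 1, Wo = W - kw + 1;
  if (Ho <= 0 || Wo <= 0) stop("kernel larger than input");
  if (w.nrow() != kh * kw * cin_g) stop("weight shape mismatch");

  NumericVector y((std::size_t)Ho * Wo * cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);

  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat Kt(Ho * Wo, kh * kw * cin_g);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xc = x.begin() + (((std::size_t)n * C) + g * cin_g) * H * W;
      im2col_group(xc, H, W, cin_g, kh, kw, Ho, Wo, Kt);
      arma::mat Yg(y.begin() + (((std::size_t)n * cout) + g * cout_g) * Ho * Wo,
                   Ho * Wo, cout_g, false, true);
      Yg = Kt * Wm.cols(g * cout_g, (g + 1) * cout_g - 1);
      for (int oc = 0; oc < cout_g; ++oc) Yg.col(oc) += b[g * cout_g + oc];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector gy,
                    int kh, int kw, int groups) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int cin_g = C / groups;
  int cout = w.ncol();
  int cout_g = cout / groups;
  int Ho = H - kh + 1, Wo = W - kw + 1;

  NumericVector gx((std::size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericMatrix gw(w.nrow(), w.ncol());
  NumericVector gb(cout);

  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat gWm(gw.begin(), gw.nrow(), gw.ncol(), false);
  arma::mat Kt(Ho * Wo, kh * kw * cin_g);
  arma::mat gKt(Ho * Wo, kh * kw * cin_g);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xc = x.begin() + (((std::size_t)n * C) + g * cin_g) * H * W;
      im2col_group(xc, H, W, cin_g, kh, kw, Ho, Wo, Kt);
      arma::mat gYg(gy.begin() + (((std::size_t)n * cout) + g * cout_g) * Ho * Wo,
                    Ho * Wo, cout_g, false, true);
      gWm.cols(g * cout_g, (g + 1) * cout_g - 1) += Kt.t() * gYg;
      for (int oc = 0; oc < cout_g; ++oc)
        gb[g * cout_g + oc] += arma::accu(gYg.col(oc));
      gKt = gYg * Wm.cols(g * cout_g, (g + 1) * cout_g - 1).t();
      // col2im scatter-add
      double* gxc = gx.begin() + (((std::size_t)n * C) + g * cin_g) * H * W;
      for (int cc = 0; cc < cin_g; ++cc) {
        double* ch = gxc + (std::size_t)cc * H * W;
        for (int j = 0; j < kw; ++j) {
          for (int i = 0; i < kh; ++i) {
            int r = cc * kh * kw + j * kh + i;
            const double* src = gKt.colptr(r);
            for (int wo = 0; wo < Wo; ++wo) {
              double* dst = ch + (std::size_t)(j + wo) * H + i;
              const double* s = src + (std::size_t)wo * Ho;
              for (int ho = 0; ho < Ho; ++ho) dst[ho] += s[ho];
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int ph, int pw) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / ph, Wo = W / pw;
  NumericVector y((std::size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((std::size_t)Ho * Wo * C * N);  // 1-based index into x

  std::size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* ch = x.begin() + (((std::size_t)n * C) + c) * H * W;
      std::size_t base = (((std::size_t)n * C) + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL;
          std::size_t bi = 0;
          for (int j = 0; j < pw; ++j) {
            for (int i = 0; i < ph; ++i) {
              std::size_t k = (std::size_t)(wo * pw + j) * H + ho * ph + i;
              if (ch[k] > best) { best = ch[k]; bi = k; }
            }
          }
          // y layout: (Ho, Wo, C, N), ho fastest => linear index
          std::size_t oy = base / ((std::size_t)H * W) * Ho * Wo +
                           (std::size_t)wo * Ho + ho;
          y[oy] = best;
          idx[oy] = (int)(base + bi) + 1;
          ++q;
        }
      }
    }
  }
  (void)q;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector gy,
                              IntegerVector xdim) {
  std::size_t n = (std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t k = 0; k < gy.size(); ++k) gx[idx[k] - 1] += gy[k];
  return gx;
}
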