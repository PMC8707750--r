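// Minimal conv/pool kernels for the heterogeneous gaze CNN.
// Layout conventions (column-major, matching R arrays):
//   image batch  x4 : [H, W, C, N]
//   conv weights w  : (k*k*Cin) x Cout, row index = dh + k*dw + k*k*c
//   conv output     : [OH, OW, Cout, N]
// im2col columns are output positions (oh fastest), so a conv is one GEMM
// per image; gradients reuse the same patch geometry via col2im.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_side(int side, int k, int stride) {
  return (side - k) / stride + 1;
}

static void im2col_one(const double* x, int H, int W, int C, int k, int stride,
                       arma::mat& cols) {
  const int OH = out_side(H, k, stride), OW = out_side(W, k, stride);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      double* dst = cols.colptr(ow * OH + oh);
      const int h0 = oh * stride, w0 = ow * stride;
      for (int c = 0; c < C; ++c) {
        const double* plane = x + (size_t)c * H * W;
        for (int dw = 0; dw < k; ++dw) {
          std::memcpy(dst, plane + (size_t)(w0 + dw) * H + h0,
                      k * sizeof(double));
          dst += k;
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& cols, int H, int W, int C, int k,
                       int stride, double* dx) {
  const int OH = out_side(H, k, stride), OW = out_side(W, k, stride);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const double* src = cols.colptr(ow * OH + oh);
      const int h0 = oh * stride, w0 = ow * stride;
      for (int c = 0; c < C; ++c) {
        double* plane = dx + (size_t)c * H * W;
        for (int dw = 0; dw < k; ++dw) {
          double* col = plane + (size_t)(w0 + dw) * H + h0;
          for (int dh = 0; dh < k; ++dh) col[dh] += src[dh];
          src += k;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x4, NumericMatrix w, NumericVector b,
                       int k, int stride) {
  IntegerVector d = x4.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.ncol();
  const int OH = out_side(H, k, stride), OW = out_side(W, k, stride);
  const int P = OH * OW;
  if (w.nrow() != k * k * C) stop("weight rows do not match k*k*Cin");

  NumericVector y4(Rf_allocVector(REALSXP, (R_xlen_t)P * Cout * N));
  y4.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  const arma::mat W_(const_cast<double*>(w.begin()), w.nrow(), Cout, false);
  const arma::vec b_(const_cast<double*>(b.begin()), Cout, false);
  arma::mat cols(k * k * C, P);

  for (int n = 0; n < N; ++n) {
    im2col_one(&x4[(size_t)n * H * W * C], H, W, C, k, stride, cols);
    arma::mat yt = cols.t() * W_;          // P x Cout; column = channel plane
    yt.each_row() += b_.t();
    std::memcpy(&y4[(size_t)n * P * Cout], yt.memptr(),
                (size_t)P * Cout * sizeof(double));
  }
  return y4;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x4, NumericMatrix w, NumericVector dy4, int k,
              int stride) {
  IntegerVector d = x4.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.ncol();
  const int OH = out_side(H, k, stride), OW = out_side(W, k, stride);
  const int P = OH * OW;

  NumericVector dx4(Rf_allocVector(REALSXP, x4.size()));
  std::fill(dx4.begin(), dx4.end(), 0.0);
  dx4.attr("dim") = d;
  const arma::mat W_(const_cast<double*>(w.begin()), w.nrow(), Cout, false);
  arma::mat dw(w.nrow(), Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(k * k * C, P);

  for (int n = 0; n < N; ++n) {
    const arma::mat dyt(const_cast<double*>(&dy4[(size_t)n * P * Cout]), P,
                        Cout, false);                 // P x Cout
    im2col_one(&x4[(size_t)n * H * W * C], H, W, C, k, stride, cols);
    dw += cols * dyt;                                 // (kkC) x Cout
    db += arma::sum(dyt, 0).t();
    arma::mat dcols = W_ * dyt.t();                   // (kkC) x P
    col2im_acc(dcols, H, W, C, k, stride, &dx4[(size_t)n * H * W * C]);
  }
  return List::create(_["dx"] = dx4, _["dw"] = wrap(dw), _["db"] = wrap(db));
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x4, int k, int stride) {
  IntegerVector d = x4.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int OH = out_side(H, k, stride), OW = out_side(W, k, stride);
  const R_xlen_t ylen = (R_xlen_t)OH * OW * C * N;

  NumericVector y(Rf_allocVector(REALSXP, ylen));
  IntegerVector amax(Rf_allocVector(INTSXP, ylen));  // 0-based index into x4
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);

  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    const size_t base_n = (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const size_t base = base_n + (size_t)c * H * W;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh, ++o) {
          const int h0 = oh * stride, w0 = ow * stride;
          double best = R_NegInf;
          size_t bidx = 0;
          for (int dw = 0; dw < k; ++dw) {
            const size_t coloff = base + (size_t)(w0 + dw) * H + h0;
            for (int dh = 0; dh < k; ++dh) {
              const double v = x4[coloff + dh];
              if (v > best) { best = v; bidx = coloff + dh; }
            }
          }
          y[o] = best;
          amax[o] = (int)bidx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector amax,
                          R_xlen_t xlen) {
  NumericVector dx(Rf_allocVector(REALSXP, xlen));
  std::fill(dx.begin(), dx.end(), 0.0);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[amax[i]] += dy[i];
  return dx;
}
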