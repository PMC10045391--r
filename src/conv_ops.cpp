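// Minimal 2D convolution kernels (im2col + GEMM) used by the network code.
// Layout conventions, chosen to match R's column-major arrays:
//   images  : arma::cube (H, W, C)
//   weights : arma::mat  (k*k*Cin, Cout); row index = c*k*k + kc*k + kr
//   outputs : arma::cube (Ho, Wo, Cout)
// Transposed convolution is expressed in R as the adjoint of these three.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat im2col(const cube& x, int k, int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat P(k * k * C, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const int col = ow * Ho + oh;
        const int r0 = oh * stride - pad;
        const int c0 = ow * stride - pad;
        for (int kc = 0; kc < k; ++kc) {
          const int cc = c0 + kc;
          if (cc < 0 || cc >= W) continue;
          for (int kr = 0; kr < k; ++kr) {
            const int rr = r0 + kr;
            if (rr < 0 || rr >= H) continue;
            P(c * k * k + kc * k + kr, col) = x(rr, cc, c);
          }
        }
      }
    }
  }
  return P;
}

static void col2im_acc(cube& dx, const mat& dP, int k, int stride, int pad,
                       int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const int col = ow * Ho + oh;
        const int r0 = oh * stride - pad;
        const int c0 = ow * stride - pad;
        for (int kc = 0; kc < k; ++kc) {
          const int cc = c0 + kc;
          if (cc < 0 || cc >= W) continue;
          for (int kr = 0; kr < k; ++kr) {
            const int rr = r0 + kr;
            if (rr < 0 || rr >= H) continue;
            dx(rr, cc, c) += dP(c * k * k + kc * k + kr, col);
          }
        }
      }
    }
  }
}

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& w, int k,
                        int stride, int pad) {
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = w.n_cols;
  mat P = im2col(x, k, stride, pad, Ho, Wo);
  mat Y = w.t() * P;  // (Cout, Ho*Wo)
  cube out(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = reshape(Y.row(co), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv_bwd_input(const arma::cube& dy, const arma::mat& w, int k,
                              int stride, int pad, int Hin, int Win, int Cin) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  mat dY(Cout, Ho * Wo);
  for (int co = 0; co < Cout; ++co)
    dY.row(co) = vectorise(dy.slice(co)).t();
  mat dP = w * dY;  // (k*k*Cin, Ho*Wo)
  cube dx(Hin, Win, Cin, fill::zeros);
  col2im_acc(dx, dP, k, stride, pad, Ho, Wo);
  return dx;
}

// [[Rcpp::export]]
arma::mat cpp_conv_bwd_weight(const arma::cube& x, const arma::cube& dy, int k,
                              int stride, int pad) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  mat P = im2col(x, k, stride, pad, Ho, Wo);
  mat dY(Cout, Ho * Wo);
  for (int co = 0; co < Cout; ++co)
    dY.row(co) = vectorise(dy.slice(co)).t();
  return P * dY.t();  // (k*k*Cin, Cout)
}
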