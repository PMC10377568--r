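// Convolution primitives for the translation models: im2col gather + GEMM
// forward, and the adjoint scatter backward.  Only the hot inner loops live
// here; layer bookkeeping stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// x: (H, W, C) array flattened column-major; W_mat: (k*k*C) x Cout with
// kernel offsets ordered d_row fastest within each input-channel block.
// [[Rcpp::export]]
List conv2d_fwd(const arma::vec& x, int H, int W, int C,
                const arma::mat& W_mat, const arma::vec& b,
                int k, int stride, int pad, bool want_cols) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = (Hp - k) / stride + 1, Wo = (Wp - k) / stride + 1;
  const int n_out = Ho * Wo, k2 = k * k;
  arma::mat cols(n_out, k2 * C, arma::fill::zeros);

  for (int c = 0; c < C; ++c) {
    const double* xc = x.memptr() + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k2 + dj * k + di;
        double* dst = cols.colptr(col);
        for (int oc = 0; oc < Wo; ++oc) {
          const int cim = oc * stride + dj - pad;
          if (cim < 0 || cim >= W) continue;
          const double* src = xc + (std::size_t)cim * H;
          double* d0 = dst + (std::size_t)oc * Ho;
          for (int orow = 0; orow < Ho; ++orow) {
            const int rim = orow * stride + di - pad;
            if (rim >= 0 && rim < H) d0[orow] = src[rim];
          }
        }
      }
    }
  }
  arma::mat out = cols * W_mat;
  out.each_row() += b.t();
  if (!want_cols)
    return List::create(_["out"] = out, _["cols"] = R_NilValue,
                        _["Ho"] = Ho, _["Wo"] = Wo);
  return List::create(_["out"] = out, _["cols"] = cols,
                      _["Ho"] = Ho, _["Wo"] = Wo);
}

// dout: (Ho*Wo) x Cout; returns input gradient (H, W, C) plus dW, db
// [[Rcpp::export]]
List conv2d_bwd(const arma::mat& cols, const arma::mat& W_mat,
                const arma::mat& dout, int H, int W, int C,
                int k, int stride, int pad, bool want_wgrad) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = (Hp - k) / stride + 1, Wo = (Wp - k) / stride + 1;
  const int k2 = k * k;
  arma::mat dW;
  arma::rowvec db;
  if (want_wgrad) {
    dW = cols.t() * dout;
    db = arma::sum(dout, 0);
  }
  arma::mat dcols = dout * W_mat.t();
  arma::vec dx((std::size_t)H * W * C, arma::fill::zeros);

  for (int c = 0; c < C; ++c) {
    double* dxc = dx.memptr() + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k2 + dj * k + di;
        const double* src = dcols.colptr(col);
        for (int oc = 0; oc < Wo; ++oc) {
          const int cim = oc * stride + dj - pad;
          if (cim < 0 || cim >= W) continue;
          double* dst = dxc + (std::size_t)cim * H;
          const double* s0 = src + (std::size_t)oc * Ho;
          for (int orow = 0; orow < Ho; ++orow) {
            const int rim = orow * stride + di - pad;
            if (rim >= 0 && rim < H) dst[rim] += s0[orow];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
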