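// im2col / col2im kernels for stride-s "same"-padded 2-D convolution.
// Layout contract (shared with R/autodiff.R):
//   feature maps are (H, W, C) arrays; patch-row index is
//   i + kh*j + kh*kw*c (matches R's column-major flattening of a
//   (kh, kw, C, ...) kernel array); output positions are column-major
//   over (oh, ow).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, int kh, int kw, int sh, int sw,
                     int pt, int pl, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(kh * kw * C, oh * ow, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * j + kh * kw * c;
        for (int wo = 0; wo < ow; ++wo) {
          const int wi = wo * sw - pl + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < oh; ++ho) {
            const int hi = ho * sh - pt + i;
            if (hi < 0 || hi >= H) continue;
            cols(r, ho + oh * wo) = x(hi, wi, c);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-accumulate patch columns back into an
// (H, W, C) array. Used both for conv backward-data and for the forward
// pass of the transposed convolution.
// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& cols, int H, int W, int C,
                      int kh, int kw, int sh, int sw,
                      int pt, int pl, int oh, int ow) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * j + kh * kw * c;
        for (int wo = 0; wo < ow; ++wo) {
          const int wi = wo * sw - pl + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < oh; ++ho) {
            const int hi = ho * sh - pt + i;
            if (hi < 0 || hi >= H) continue;
            x(hi, wi, c) += cols(r, ho + oh * wo);
          }
        }
      }
    }
  }
  return x;
}
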