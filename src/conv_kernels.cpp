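// im2col kernels for the same-padded 3x3 convolution. Feature maps are
// channels-first (C x H*W*N); idx holds 1-based neighbour columns per
// 3x3 offset, with out-of-image neighbours pointing one past the last
// column (read as zero, dropped on scatter). The 9 offset weight slabs
// (c_out x c_in x 9) are viewed as one (c_out x 9*c_in) matrix so each
// direction is a single BLAS product over the gathered patch matrix.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::vec;

// gather the (9*c_in) x n patch matrix
static void im2col(const mat& X, const Rcpp::IntegerMatrix& idx, mat& P) {
  const int n = X.n_cols;
  const int c_in = X.n_rows;
  const double* xp = X.memptr();
  double* pp = P.memptr();
  const int prows = 9 * c_in;
  for (int o = 0; o < 9; ++o) {
    const int roff = o * c_in;
    for (int j = 0; j < n; ++j) {
      double* dst = pp + (size_t)j * prows + roff;
      const int k = idx(j, o) - 1;
      if (k < n) {
        const double* src = xp + (size_t)k * c_in;
        for (int c = 0; c < c_in; ++c) dst[c] = src[c];
      } else {
        for (int c = 0; c < c_in; ++c) dst[c] = 0.0;
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat conv3_fwd_cpp(const arma::mat& X, const Rcpp::IntegerMatrix& idx,
                        const Rcpp::NumericVector& W9, const arma::vec& b) {
  Rcpp::IntegerVector dims = W9.attr("dim");
  const int c_out = dims[0], c_in = dims[1];
  const mat W2(const_cast<double*>(W9.begin()), c_out, 9 * c_in, false);
  const int n = X.n_cols;
  mat P(9 * c_in, n);
  im2col(X, idx, P);
  mat Y = W2 * P;
  Y.each_col() += b;
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3_bwd_cpp(const arma::mat& X, const arma::mat& dY,
                         const Rcpp::IntegerMatrix& idx,
                         const Rcpp::NumericVector& W9) {
  Rcpp::IntegerVector dims = W9.attr("dim");
  const int c_out = dims[0], c_in = dims[1];
  const mat W2(const_cast<double*>(W9.begin()), c_out, 9 * c_in, false);
  const int n = X.n_cols;
  mat P(9 * c_in, n);
  im2col(X, idx, P);
  mat dW2 = dY * P.t();
  mat dP = W2.t() * dY;                  // (9*c_in) x n
  mat dX(c_in, n, arma::fill::zeros);
  const double* dpp = dP.memptr();
  double* dxp = dX.memptr();
  const int prows = 9 * c_in;
  for (int o = 0; o < 9; ++o) {
    const int roff = o * c_in;
    for (int j = 0; j < n; ++j) {
      const int k = idx(j, o) - 1;
      if (k < n) {
        const double* src = dpp + (size_t)j * prows + roff;
        double* dst = dxp + (size_t)k * c_in;
        for (int c = 0; c < c_in; ++c) dst[c] += src[c];
      }
    }
  }
  Rcpp::NumericVector dWout = Rcpp::wrap(vec(dW2.memptr(), dW2.n_elem));
  dWout.attr("dim") = Rcpp::IntegerVector::create(c_out, c_in, 9);
  return Rcpp::List::create(Rcpp::Named("dW") = dWout,
                            Rcpp::Named("dX") = dX);
}
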