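// 3D convolution kernels (kernel size 3, "same" padding, stride 1 or 2)
// for the registration network. Feature maps are dense matrices
// (n_voxels x channels); the convolution is evaluated as an im2col gather
// followed by a BLAS product, and the backward pass scatters the gathered
// gradient back onto the grid. The im2col matrix is allocated as R memory
// and handed back to the caller so the backward pass can reuse it without
// a copy.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void out_sizes(const ivec& d, int stride, ivec& od) {
  od.set_size(3);
  for (int a = 0; a < 3; ++a) od[a] = (d[a] + stride - 1) / stride;
}

// fill an im2col matrix: rows = output voxels (axis 1 fastest), columns =
// channels within kernel offset, offsets ordered axis-1 fastest
static void im2col_fill(mat& M, const mat& x, const ivec& d, int stride,
                        const ivec& od) {
  const int C = x.n_cols;
  for (int c3 = -1; c3 <= 1; ++c3)
    for (int c2 = -1; c2 <= 1; ++c2)
      for (int c1 = -1; c1 <= 1; ++c1) {
        const int k = (c1 + 1) + 3 * (c2 + 1) + 9 * (c3 + 1);
        for (int ch = 0; ch < C; ++ch) {
          const double* src = x.colptr(ch);
          double* dst = M.colptr(k * C + ch);
          long long r = 0;
          for (int k3 = 0; k3 < od[2]; ++k3) {
            const int i3 = k3 * stride + c3;
            const bool ok3 = i3 >= 0 && i3 < d[2];
            for (int k2 = 0; k2 < od[1]; ++k2) {
              const int i2 = k2 * stride + c2;
              const bool ok23 = ok3 && i2 >= 0 && i2 < d[1];
              const long long base =
                  (long long)i2 * d[0] + (long long)i3 * d[0] * d[1];
              for (int k1 = 0; k1 < od[0]; ++k1, ++r) {
                const int i1 = k1 * stride + c1;
                dst[r] = (ok23 && i1 >= 0 && i1 < d[0]) ? src[base + i1] : 0.0;
              }
            }
          }
        }
      }
}

// [[Rcpp::export]]
Rcpp::List conv3_fwd_cpp(const arma::mat& x, const arma::ivec& dims,
                         int stride, const arma::mat& W,
                         const arma::vec& b, bool keep_M = false) {
  ivec od;
  out_sizes(dims, stride, od);
  const long long n_out = (long long)od[0] * od[1] * od[2];
  const int cols = 27 * x.n_cols;
  Rcpp::NumericMatrix Mr(n_out, cols);
  mat M(Mr.begin(), n_out, cols, false, true);
  im2col_fill(M, x, dims, stride, od);
  Rcpp::NumericMatrix yr(n_out, W.n_cols);
  mat y(yr.begin(), n_out, W.n_cols, false, true);
  y = M * W;
  y.each_row() += b.t();
  if (keep_M)
    return Rcpp::List::create(Rcpp::Named("y") = yr,
                              Rcpp::Named("shape") = od,
                              Rcpp::Named("M") = Mr);
  return Rcpp::List::create(Rcpp::Named("y") = yr,
                            Rcpp::Named("shape") = od);
}

// scatter the im2col-layout gradient back onto the input grid
static void col2im_scatter(mat& dX, const mat& dM, const ivec& d, int stride,
                           const ivec& od, int C) {
  for (int c3 = -1; c3 <= 1; ++c3)
    for (int c2 = -1; c2 <= 1; ++c2)
      for (int c1 = -1; c1 <= 1; ++c1) {
        const int k = (c1 + 1) + 3 * (c2 + 1) + 9 * (c3 + 1);
        for (int ch = 0; ch < C; ++ch) {
          const double* src = dM.colptr(k * C + ch);
          double* dst = dX.colptr(ch);
          long long r = 0;
          for (int k3 = 0; k3 < od[2]; ++k3) {
            const int i3 = k3 * stride + c3;
            const bool ok3 = i3 >= 0 && i3 < d[2];
            for (int k2 = 0; k2 < od[1]; ++k2) {
              const int i2 = k2 * stride + c2;
              const bool ok23 = ok3 && i2 >= 0 && i2 < d[1];
              const long long base =
                  (long long)i2 * d[0] + (long long)i3 * d[0] * d[1];
              for (int k1 = 0; k1 < od[0]; ++k1, ++r) {
                const int i1 = k1 * stride + c1;
                if (ok23 && i1 >= 0 && i1 < d[0]) dst[base + i1] += src[r];
              }
            }
          }
        }
      }
}

// backward pass recomputing im2col from the cached input
// [[Rcpp::export]]
Rcpp::List conv3_bwd_cpp(const arma::mat& dY, const arma::mat& x,
                         const arma::ivec& dims, int stride,
                         const arma::mat& W) {
  const int C = x.n_cols;
  ivec od;
  out_sizes(dims, stride, od);
  const long long n_out = (long long)od[0] * od[1] * od[2];
  mat M(n_out, 27 * C);
  im2col_fill(M, x, dims, stride, od);
  mat dW = M.t() * dY;
  vec db = sum(dY, 0).t();
  mat dM = dY * W.t();
  Rcpp::NumericMatrix dXr(x.n_rows, C);
  mat dX(dXr.begin(), x.n_rows, C, false, true);
  col2im_scatter(dX, dM, dims, stride, od, C);
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dXr);
}

// backward pass reusing the forward's im2col matrix (no copy)
// [[Rcpp::export]]
Rcpp::List conv3_bwd_m_cpp(const arma::mat& dY, Rcpp::NumericMatrix Mr,
                           double n_in, const arma::ivec& dims,
                           int stride, const arma::mat& W) {
  const int C = W.n_rows / 27;
  const mat M(Mr.begin(), Mr.nrow(), Mr.ncol(), false, true);
  ivec od;
  out_sizes(dims, stride, od);
  mat dW = M.t() * dY;
  vec db = sum(dY, 0).t();
  mat dM = dY * W.t();
  Rcpp::NumericMatrix dXr((long long)n_in, C);
  mat dX(dXr.begin(), (long long)n_in, C, false, true);
  col2im_scatter(dX, dM, dims, stride, od, C);
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dXr);
}
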