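// Minimal 2-D convolution kernels for the U-Net generator and the
// convolutional discriminator.  Tensors are arma::cube with slices as
// channels (H x W x C).  Convolution weights are stored as a matrix of
// size C_out x (k*k*C_in); transposed convolution reuses the same layout
// through the adjoint relations (its forward pass is the data-backward
// pass of the mirrored convolution).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Plain-loop matrix products.  The training loop feeds its own outputs
// back through these kernels thousands of times, so their arithmetic
// must be bitwise reproducible across machines; BLAS backends select
// CPU-specific kernels with different summation orders, which would let
// two hosts diverge.  Sizes here are small enough that explicit loops
// cost little.
static mat mm(const mat &A, const mat &B) {          // A * B
  mat C(A.n_rows, B.n_cols, fill::zeros);
  for (uword j = 0; j < B.n_cols; ++j)
    for (uword k = 0; k < A.n_cols; ++k) {
      const double b = B(k, j);
      if (b == 0.0) continue;
      for (uword i = 0; i < A.n_rows; ++i) C(i, j) += A(i, k) * b;
    }
  return C;
}

static mat mtm(const mat &A, const mat &B) {         // A.t() * B
  mat C(A.n_cols, B.n_cols, fill::zeros);
  for (uword j = 0; j < B.n_cols; ++j)
    for (uword i = 0; i < A.n_cols; ++i) {
      double s = 0.0;
      for (uword k = 0; k < A.n_rows; ++k) s += A(k, i) * B(k, j);
      C(i, j) = s;
    }
  return C;
}

static mat mmt(const mat &A, const mat &B) {         // A * B.t()
  mat C(A.n_rows, B.n_rows, fill::zeros);
  for (uword k = 0; k < A.n_cols; ++k)
    for (uword j = 0; j < B.n_rows; ++j) {
      const double b = B(j, k);
      if (b == 0.0) continue;
      for (uword i = 0; i < A.n_rows; ++i) C(i, j) += A(i, k) * b;
    }
  return C;
}

// im2col: rows indexed by (ci, kj, ki) channel-major, columns by output
// position p = i + Ho * j (column-major over the output grid).
static mat im2col(const cube &x, int k, int stride, int pad,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(k * k * C, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat &xs = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride + kj - pad;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int wi = i * stride + ki - pad;
            if (wi < 0 || wi >= H) continue;
            cols(r, i + Ho * j) = xs(wi, wj);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat &cols, int k, int stride, int pad,
                   int H, int W, int C, int Ho, int Wo) {
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat &xs = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride + kj - pad;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int wi = i * stride + ki - pad;
            if (wi < 0 || wi >= H) continue;
            xs(wi, wj) += cols(r, i + Ho * j);
          }
        }
      }
    }
  }
  return x;
}

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube &x, const arma::mat &W,
                       const arma::vec &b, int k, int stride, int pad) {
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = W.n_rows;
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat o = mm(W, cols);         // Cout x (Ho*Wo)
  o.each_col() += b;
  cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(o.row(c).t(), Ho, Wo);
  return out;
}

// Backward pass of nn_conv_fwd.  want_gx = false skips the (unused)
// input gradient when only the weight gradient is needed (transposed
// convolution weight update).
// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube &x, const arma::mat &W,
                       const arma::cube &gout, int k, int stride, int pad,
                       bool want_gx) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, Cout = gout.n_slices;
  mat gmat(Cout, Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    gmat.row(c) = vectorise(gout.slice(c)).t();
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat gW = mmt(gmat, cols);
  vec gb = sum(gmat, 1);
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("gW") = gW,
                                      Rcpp::Named("gb") = gb);
  if (want_gx) {
    mat gcols = mtm(W, gmat);
    res["gx"] = col2im(gcols, k, stride, pad,
                       x.n_rows, x.n_cols, x.n_slices, Ho, Wo);
  }
  return res;
}

// Data-backward of a convolution, used directly as the forward pass of
// the transposed convolution: scatters `gout` (the small tensor) into an
// output of size H x W with C channels (= C_in of the mirrored conv).
// [[Rcpp::export]]
arma::cube nn_conv_bwd_data(const arma::mat &W, const arma::cube &gout,
                            int k, int stride, int pad,
                            int H, int Wd, int C) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, Cout = gout.n_slices;
  mat gmat(Cout, Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    gmat.row(c) = vectorise(gout.slice(c)).t();
  mat gcols = mtm(W, gmat);
  return col2im(gcols, k, stride, pad, H, Wd, C, Ho, Wo);
}
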