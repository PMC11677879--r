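// Minimal 2-D convolution primitives for the compact encoder-decoder networks.
// Layout: activations are (H, W, C) cubes; kernel matrices are
// (C_out, C_in * k * k) with patch index (c_in * k + ki) * k + kj, where
// (ki, kj) run over kernel rows/cols. Zero padding, square kernels, integer
// stride and dilation. Single image per call (batch dimension handled in R).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube &x, int k, int stride, int dil, int pad,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(C * k * k, (size_t)Ho * Wo, fill::none);
  double *out = cols.memptr();
  const double *xp = x.memptr();
  const size_t plane = (size_t)H * W;
  // column-major fill: sequential writes, local reads
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      double *col = out + ((size_t)oj * Ho + oi) * (size_t)(C * k * k);
      for (int c = 0; c < C; ++c) {
        const double *xs = xp + plane * c;
        for (int ki = 0; ki < k; ++ki) {
          const int ii = oi * stride - pad + ki * dil;
          double *dst = col + (size_t)(c * k + ki) * k;
          for (int kj = 0; kj < k; ++kj) {
            const int jj = oj * stride - pad + kj * dil;
            dst[kj] = (ii < 0 || ii >= H || jj < 0 || jj >= W)
                          ? 0.0
                          : xs[(size_t)jj * H + ii];
          }
        }
      }
    }
  }
  return cols;
}

static void out_size(int H, int W, int k, int stride, int dil, int pad,
                     int &Ho, int &Wo) {
  const int eff = (k - 1) * dil + 1;
  Ho = (H + 2 * pad - eff) / stride + 1;
  Wo = (W + 2 * pad - eff) / stride + 1;
  if (Ho < 1 || Wo < 1) Rcpp::stop("convolution output would be empty");
}

static cube mat_to_cube(const mat &y, int Ho, int Wo) {
  cube out(Ho, Wo, y.n_rows);
  for (uword c = 0; c < y.n_rows; ++c) {
    out.slice(c) = reshape(y.row(c), Ho, Wo);
  }
  return out;
}

// [[Rcpp::export(name = ".conv_fwd")]]
arma::cube conv_fwd(const arma::cube &x, const arma::mat &Wm,
                    const arma::vec &b, int k, int stride, int dil, int pad) {
  int Ho, Wo;
  out_size(x.n_rows, x.n_cols, k, stride, dil, pad, Ho, Wo);
  mat cols = im2col(x, k, stride, dil, pad, Ho, Wo);
  mat y = Wm * cols;
  y.each_col() += b;
  return mat_to_cube(y, Ho, Wo);
}

// Forward pass that also returns the patch matrix for reuse in the backward
// pass during training.
// [[Rcpp::export(name = ".conv_fwd_train")]]
Rcpp::List conv_fwd_train(const arma::cube &x, const arma::mat &Wm,
                          const arma::vec &b, int k, int stride, int dil,
                          int pad) {
  int Ho, Wo;
  out_size(x.n_rows, x.n_cols, k, stride, dil, pad, Ho, Wo);
  mat cols = im2col(x, k, stride, dil, pad, Ho, Wo);
  mat y = Wm * cols;
  y.each_col() += b;
  return Rcpp::List::create(Rcpp::Named("y") = mat_to_cube(y, Ho, Wo),
                            Rcpp::Named("cols") = cols);
}

// Gradients w.r.t. parameters and input, reusing the cached patch matrix.
// dy is (Ho, Wo, Cout); xdim = c(H, W, C) of the forward input.
// [[Rcpp::export(name = ".conv_bwd")]]
Rcpp::List conv_bwd(const arma::mat &cols, const arma::mat &Wm,
                    const arma::cube &dy, Rcpp::IntegerVector xdim, int k,
                    int stride, int dil, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  mat dymat(Cout, (size_t)Ho * Wo);
  for (int c = 0; c < Cout; ++c) {
    dymat.row(c) = vectorise(dy.slice(c)).t();
  }
  mat dW = dymat * cols.t();
  vec db = sum(dymat, 1);
  mat dcols = Wm.t() * dymat;
  cube dx(H, W, C, fill::zeros);  // col2im accumulation
  double *dxp = dx.memptr();
  const double *dcp = dcols.memptr();
  const size_t plane = (size_t)H * W;
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const double *col = dcp + ((size_t)oj * Ho + oi) * (size_t)(C * k * k);
      for (int c = 0; c < C; ++c) {
        double *xs = dxp + plane * c;
        for (int ki = 0; ki < k; ++ki) {
          const int ii = oi * stride - pad + ki * dil;
          if (ii < 0 || ii >= H) continue;
          const double *src = col + (size_t)(c * k + ki) * k;
          for (int kj = 0; kj < k; ++kj) {
            const int jj = oj * stride - pad + kj * dil;
            if (jj < 0 || jj >= W) continue;
            xs[(size_t)jj * H + ii] += src[kj];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
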