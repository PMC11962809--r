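// Batched 1-D convolution and max-pooling kernels for the CNN engine.
// Layout: signals travel as arma::cube [channels x time x batch];
// conv weights as arma::mat [out_channels x (in_channels * kernel)].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline uword conv_out_len(uword L, uword k, uword stride) {
  return (L - k) / stride + 1;
}

// Unfold one slice into im2col layout: rows = ic*k, cols = T_out.
// Column t holds x[, t*stride .. t*stride+k-1] stacked channel-major
// (channel varies fastest within each kernel tap).
static void im2col_slice(const mat& x, uword k, uword stride, mat& cols) {
  const uword ic = x.n_rows;
  const uword T = cols.n_cols;
  for (uword t = 0; t < T; ++t) {
    const uword s0 = t * stride;
    double* dst = cols.colptr(t);
    for (uword j = 0; j < k; ++j) {
      const double* src = x.colptr(s0 + j);
      std::memcpy(dst + j * ic, src, ic * sizeof(double));
    }
  }
}

// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::cube conv1d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, int stride, int kernel) {
  const uword ic = x.n_rows, L = x.n_cols, B = x.n_slices;
  const uword k = (uword)kernel, s = (uword)stride;
  const uword oc = W.n_rows;
  if (W.n_cols != ic * k) Rcpp::stop("weight shape mismatch");
  if (L < k) Rcpp::stop("signal shorter than kernel");
  const uword T = conv_out_len(L, k, s);
  cube y(oc, T, B);
  mat cols(ic * k, T);
  for (uword n = 0; n < B; ++n) {
    im2col_slice(x.slice(n), k, s, cols);
    y.slice(n) = W * cols;
    y.slice(n).each_col() += b;
  }
  return y;
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
Rcpp::List conv1d_bwd(const arma::cube& x, const arma::mat& W,
                      const arma::cube& dy, int stride, int kernel,
                      bool need_dx) {
  const uword ic = x.n_rows, L = x.n_cols, B = x.n_slices;
  const uword k = (uword)kernel, s = (uword)stride;
  const uword oc = W.n_rows;
  const uword T = dy.n_cols;
  mat dW(oc, ic * k, fill::zeros);
  vec db(oc, fill::zeros);
  cube dx;
  if (need_dx) dx.zeros(ic, L, B);
  mat cols(ic * k, T);
  for (uword n = 0; n < B; ++n) {
    im2col_slice(x.slice(n), k, s, cols);
    const mat& dyn = dy.slice(n);
    dW += dyn * cols.t();
    db += sum(dyn, 1);
    if (need_dx) {
      mat dcols = W.t() * dyn; // (ic*k) x T
      mat& dxn = dx.slice(n);
      for (uword t = 0; t < T; ++t) {
        const uword s0 = t * s;
        const double* src = dcols.colptr(t);
        for (uword j = 0; j < k; ++j) {
          double* dst = dxn.colptr(s0 + j);
          const double* sp = src + j * ic;
          for (uword c = 0; c < ic; ++c) dst[c] += sp[c];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}

// Non-overlapping max pool over time; trailing remainder dropped.
// [[Rcpp::export(name = ".maxpool1d_fwd")]]
Rcpp::List maxpool1d_fwd(const arma::cube& x, int width) {
  const uword C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const uword w = (uword)width;
  const uword T = L / w;
  cube y(C, T, B);
  ucube idx(C, T, B); // column index (in x) of each max
  for (uword n = 0; n < B; ++n) {
    const mat& xs = x.slice(n);
    for (uword t = 0; t < T; ++t) {
      for (uword c = 0; c < C; ++c) {
        uword best = t * w;
        double bv = xs(c, best);
        for (uword j = 1; j < w; ++j) {
          const double v = xs(c, t * w + j);
          if (v > bv) { bv = v; best = t * w + j; }
        }
        y(c, t, n) = bv;
        idx(c, t, n) = best;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool1d_bwd")]]
arma::cube maxpool1d_bwd(const arma::cube& dy, const arma::ucube& idx,
                         int in_len) {
  const uword C = dy.n_rows, T = dy.n_cols, B = dy.n_slices;
  cube dx(C, (uword)in_len, B, fill::zeros);
  for (uword n = 0; n < B; ++n) {
    for (uword t = 0; t < T; ++t) {
      for (uword c = 0; c < C; ++c) {
        dx(c, idx(c, t, n), n) += dy(c, t, n);
      }
    }
  }
  return dx;
}
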