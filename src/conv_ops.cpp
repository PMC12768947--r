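// Convolution and max-pooling kernels for the 1D CNNs.
//
// Activations for a batch of b spectra at a layer with L positions and C
// channels are a (b*L) x C matrix with row index r = sample + pos*b
// (sample fastest). A valid convolution then decomposes into `kernel`
// shifted GEMMs: the rows touched by kernel offset j are the contiguous
// block starting at j*b, so no im2col patch matrix is ever materialised.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// A: (batch*L_in) x c_in; W: (kernel*c_in) x c_out, offset-major row blocks.
// Returns pre-activation Z: (batch*L_out) x c_out (bias not added here).
// [[Rcpp::export]]
arma::mat conv_fwd_cpp(const arma::mat& A, const arma::mat& W,
                       const int batch, const int kernel) {
  const int c_in = A.n_cols;
  const int L_in = A.n_rows / batch;
  const int L_out = L_in - kernel + 1;
  const int N = batch * L_out;
  arma::mat Z(N, W.n_cols, arma::fill::zeros);
  for (int j = 0; j < kernel; ++j)
    Z += A.rows(j * batch, j * batch + N - 1) *
         W.rows(j * c_in, (j + 1) * c_in - 1);
  return Z;
}

// Gradients of the same convolution. dZ: (batch*L_out) x c_out.
// [[Rcpp::export]]
List conv_bwd_cpp(const arma::mat& A, const arma::mat& W, const arma::mat& dZ,
                  const int batch, const int kernel, const bool need_dA) {
  const int c_in = A.n_cols;
  const int N = dZ.n_rows;
  arma::mat dW(W.n_rows, W.n_cols);
  for (int j = 0; j < kernel; ++j)
    dW.rows(j * c_in, (j + 1) * c_in - 1) =
      A.rows(j * batch, j * batch + N - 1).t() * dZ;
  arma::rowvec db = arma::sum(dZ, 0);
  arma::mat dA;
  if (need_dA) {
    dA.zeros(A.n_rows, c_in);
    for (int j = 0; j < kernel; ++j)
      dA.rows(j * batch, j * batch + N - 1) +=
        dZ * W.rows(j * c_in, (j + 1) * c_in - 1).t();
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dA"] = dA);
}

// Max pooling with width = stride = pool. H: (batch*L_out) x C.
// argmax stores the winning slot (0-based) per pooled cell.
// [[Rcpp::export]]
List pool_fwd_cpp(const arma::mat& H, const int batch, const int pool) {
  const int C = H.n_cols;
  const int L_out = H.n_rows / batch;
  const int L_pool = L_out / pool;
  const int Np = batch * L_pool;
  arma::mat Out(Np, C);
  IntegerMatrix arg(Np, C);
  for (int c = 0; c < C; ++c) {
    const double* h = H.colptr(c);
    double* o = Out.colptr(c);
    for (int p = 0; p < L_pool; ++p)
      for (int b = 0; b < batch; ++b) {
        const int base = p * pool * batch + b;
        double best = h[base];
        int bq = 0;
        for (int q = 1; q < pool; ++q) {
          const double v = h[base + q * batch];
          if (v > best) { best = v; bq = q; }
        }
        o[p * batch + b] = best;
        arg(p * batch + b, c) = bq;
      }
  }
  return List::create(_["out"] = Out, _["argmax"] = arg);
}

// Pool gradient: route each pooled-cell gradient to its argmax slot.
// [[Rcpp::export]]
arma::mat pool_bwd_cpp(const arma::mat& dA, const IntegerMatrix& arg,
                       const int batch, const int pool, const int L_out) {
  const int C = dA.n_cols;
  const int L_pool = dA.n_rows / batch;
  arma::mat dH(batch * L_out, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* g = dA.colptr(c);
    double* out = dH.colptr(c);
    for (int p = 0; p < L_pool; ++p)
      for (int b = 0; b < batch; ++b) {
        const int i = p * batch + b;
        out[(p * pool + arg(i, c)) * batch + b] = g[i];
      }
  }
  return dH;
}
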