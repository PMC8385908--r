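// Memory-bound kernels of the 1-D convolutional branch: patch-matrix
// unfold/fold (im2col and its transpose), fused bias + ReLU, and width-2
// max pooling. Activations use the sample-major (N, L, C) layout, under
// which every (k, c) patch column is one contiguous block of the input.

#include <Rcpp.h>
using namespace Rcpp;

// unfold an (N, L, C) array into the (N*Lout) x (K*C) patch matrix,
// columns ordered with k fastest (matching weight rows indexed by (k, c))
// [[Rcpp::export(rng = false)]]
NumericMatrix cppIm2col(const NumericVector& X, const int N, const int L,
                        const int C, const int K) {
  const int Lout = L - K + 1;
  const R_xlen_t n = (R_xlen_t)N * Lout;
  NumericMatrix out(n, K * C);
  const double* xp = X.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < K; ++k) {
      const double* src = xp + (R_xlen_t)c * N * L + (R_xlen_t)k * N;
      double* dst = op + (R_xlen_t)(c * K + k) * n;
      std::copy(src, src + n, dst);
    }
  return out;
}

// transpose of the unfold: scatter-add patch-matrix columns back into an
// (N, L, C)-sized gradient
// [[Rcpp::export(rng = false)]]
NumericVector cppCol2im(const NumericMatrix& dXcol, const int N, const int L,
                        const int C, const int K) {
  const int Lout = L - K + 1;
  const R_xlen_t n = (R_xlen_t)N * Lout;
  NumericVector dX((R_xlen_t)N * L * C);
  const double* sp = dXcol.begin();
  double* dp = dX.begin();
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < K; ++k) {
      const double* src = sp + (R_xlen_t)(c * K + k) * n;
      double* dst = dp + (R_xlen_t)c * N * L + (R_xlen_t)k * N;
      for (R_xlen_t i = 0; i < n; ++i) dst[i] += src[i];
    }
  return dX;
}

// add the per-column bias and apply ReLU, in place (Z is always a fresh
// matmul result); returns the 0/1 activation mask for backprop
// [[Rcpp::export(rng = false)]]
NumericVector cppBiasRelu(NumericMatrix Z, const NumericVector& b) {
  const R_xlen_t n = Z.nrow();
  const int F = Z.ncol();
  NumericVector mask((R_xlen_t)n * F);
  double* zp = Z.begin();
  double* mp = mask.begin();
  for (int f = 0; f < F; ++f) {
    const double bf = b[f];
    double* col = zp + (R_xlen_t)f * n;
    double* mcol = mp + (R_xlen_t)f * n;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double v = col[i] + bf;
      if (v > 0) { col[i] = v; mcol[i] = 1.0; } else col[i] = 0.0;
    }
  }
  return mask;
}

// width-2 max pool (stride 2, remainder dropped) over dim 2 of (N, L, C);
// ties keep the earlier position; sel marks where the second element won
// [[Rcpp::export(rng = false)]]
List cppPoolFwd(const NumericVector& A, const int N, const int L, const int C) {
  const int Lp = L / 2;
  NumericVector out((R_xlen_t)N * Lp * C), sel((R_xlen_t)N * Lp * C);
  const double* ap = A.begin();
  double* op = out.begin();
  double* sp = sel.begin();
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < Lp; ++t) {
      const double* a1 = ap + (R_xlen_t)c * N * L + (R_xlen_t)(2 * t) * N;
      const double* a2 = a1 + N;
      double* o = op + (R_xlen_t)c * N * Lp + (R_xlen_t)t * N;
      double* s = sp + (R_xlen_t)c * N * Lp + (R_xlen_t)t * N;
      for (int i = 0; i < N; ++i) {
        if (a2[i] > a1[i]) { o[i] = a2[i]; s[i] = 1.0; }
        else o[i] = a1[i];
      }
    }
  return List::create(_["A"] = out, _["sel"] = sel);
}

// route pooled gradients back to the winning positions
// [[Rcpp::export(rng = false)]]
NumericVector cppPoolBwd(const NumericVector& dOut, const NumericVector& sel,
                         const int N, const int L, const int C) {
  const int Lp = L / 2;
  NumericVector dX((R_xlen_t)N * L * C);
  const double* dp = dOut.begin();
  const double* sp = sel.begin();
  double* xp = dX.begin();
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < Lp; ++t) {
      const double* d = dp + (R_xlen_t)c * N * Lp + (R_xlen_t)t * N;
      const double* s = sp + (R_xlen_t)c * N * Lp + (R_xlen_t)t * N;
      double* x1 = xp + (R_xlen_t)c * N * L + (R_xlen_t)(2 * t) * N;
      double* x2 = x1 + N;
      for (int i = 0; i < N; ++i) {
        if (s[i] > 0) x2[i] = d[i]; else x1[i] = d[i];
      }
    }
  return dX;
}
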