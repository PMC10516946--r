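#include <Rcpp.h>
using namespace Rcpp;

// im2col gather for channel-first activations.  A is (K, S*N): K channels,
// S spatial positions, N images, column-major.  P0 is (k2, So) giving for
// each kernel tap and output position the 1-based unpadded spatial source
// index, or 0 where the tap falls in the zero padding.  Output is
// (k2*K, So*N), laid out so a conv is one GEMM with the (Kout, k2*K)
// weight matrix.
// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericMatrix A, IntegerMatrix P0, int K, int S,
                         int N) {
  const int k2 = P0.nrow(), So = P0.ncol();
  NumericMatrix out(k2 * K, So * N);
  const double* a = A.begin();
  double* o = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int s = 0; s < So; ++s) {
      double* ocol = o + (size_t)(n * So + s) * (k2 * K);
      for (int q = 0; q < k2; ++q) {
        const int idx = P0(q, s);
        if (idx == 0) {
          for (int c = 0; c < K; ++c) ocol[q + c * k2] = 0.0;
        } else {
          const double* acol = a + (size_t)(n * S + idx - 1) * K;
          for (int c = 0; c < K; ++c) ocol[q + c * k2] = acol[c];
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add patch gradients (k2*K, So*N) back to the
// channel-first activation gradient (K, S*N).
// [[Rcpp::export(name = ".col2im_cpp")]]
NumericMatrix col2im_cpp(NumericMatrix dP, IntegerMatrix P0, int K, int S,
                         int N) {
  const int k2 = P0.nrow(), So = P0.ncol();
  NumericMatrix dA(K, S * N);
  const double* p = dP.begin();
  double* a = dA.begin();
  for (int n = 0; n < N; ++n) {
    for (int s = 0; s < So; ++s) {
      const double* pcol = p + (size_t)(n * So + s) * (k2 * K);
      for (int q = 0; q < k2; ++q) {
        const int idx = P0(q, s);
        if (idx == 0) continue;
        double* acol = a + (size_t)(n * S + idx - 1) * K;
        for (int c = 0; c < K; ++c) acol[c] += pcol[q + c * k2];
      }
    }
  }
  return dA;
}
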