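#include <Rcpp.h>
using namespace Rcpp;

// Unrolls a (H, W, B, C) activation array into the (H*W*B) x (k*k*C)
// im2col matrix for a stride-1 "same" convolution with pad_before = pb
// zero rows/columns on the top/left (total padding k-1).  Column q
// enumerates (kernel row, kernel col, channel), kernel row fastest,
// matching the (k*k*C) x Cout weight-matrix row order.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int B, int C,
                         int k, int pb) {
  const int HW = H * W;
  const R_xlen_t n = (R_xlen_t)HW * B;
  NumericMatrix M(n, (R_xlen_t)k * k * C);
  double* mp = REAL(M);
  const double* xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * HW * B;
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        double* col = mp + (R_xlen_t)((c * k + b) * k + a) * n;
        const int di = a - pb;
        const int dj = b - pb;
        for (int s = 0; s < B; ++s) {
          const double* xs = xc + (R_xlen_t)s * HW;
          double* cs = col + (R_xlen_t)s * HW;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj;
            double* cj = cs + (R_xlen_t)j * H;
            if (sj < 0 || sj >= W) {
              std::fill(cj, cj + H, 0.0);
              continue;
            }
            const double* xj = xs + (R_xlen_t)sj * H;
            const int i0 = di < 0 ? -di : 0;
            const int i1 = di > 0 ? H - di : H;
            if (i0 > 0) std::fill(cj, cj + i0, 0.0);
            if (i1 > i0) std::copy(xj + i0 + di, xj + i1 + di, cj + i0);
            if (i1 < H) std::fill(cj + i1, cj + H, 0.0);
          }
        }
      }
    }
  }
  return M;
}
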