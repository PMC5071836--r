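#include <Rcpp.h>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Online SOM training on a toroidal grid.
//
// X:      n x D data matrix
// W:      (rows*cols) x D initial weights, unit u = r*cols + c (0-based, row-major)
// order0: n x epochs matrix of 0-based presentation orders
// lr, radius: per-epoch learning rate and neighbourhood radius
// kernel: 0 = Gaussian exp(-d^2 / (2 radius^2)), 1 = cone max(0, 1 - d/radius)
//
// Grid distance is Euclidean under the minimum-image convention per axis.
// BMU ties are broken toward the smallest row-major linear index.
// [[Rcpp::export]]
NumericMatrix esom_train_cpp(const NumericMatrix& X, const NumericMatrix& W,
                             int rows, int cols,
                             const IntegerMatrix& order0,
                             const NumericVector& lr,
                             const NumericVector& radius,
                             int kernel) {
  const int n = X.nrow(), D = X.ncol();
  const int U = rows * cols;
  const int E = order0.ncol();
  if (W.nrow() != U || W.ncol() != D) stop("weight matrix shape mismatch");
  if (order0.nrow() != n) stop("presentation order shape mismatch");
  NumericMatrix Wk = clone(W);

  for (int e = 0; e < E; ++e) {
    const double a = lr[e];
    const double rad = radius[e];
    const double denom = 2.0 * rad * rad;
    for (int s = 0; s < n; ++s) {
      const int i = order0(s, e);
      // best matching unit
      int best = 0;
      double bestd = R_PosInf;
      for (int u = 0; u < U; ++u) {
        double d2 = 0.0;
        for (int d = 0; d < D; ++d) {
          const double t = Wk(u, d) - X(i, d);
          d2 += t * t;
        }
        if (d2 < bestd) { bestd = d2; best = u; }
      }
      const int br = best / cols, bc = best % cols;
      // neighbourhood update of every unit
      for (int u = 0; u < U; ++u) {
        int dr = std::abs(u / cols - br);
        if (rows - dr < dr) dr = rows - dr;
        int dc = std::abs(u % cols - bc);
        if (cols - dc < dc) dc = cols - dc;
        const double g2 = (double)dr * dr + (double)dc * dc;
        double h;
        if (kernel == 0) {
          h = std::exp(-g2 / denom);
        } else {
          const double gd = std::sqrt(g2);
          h = gd >= rad ? 0.0 : 1.0 - gd / rad;
        }
        if (h < 1e-12) continue;
        const double ah = a * h;
        for (int d = 0; d < D; ++d)
          Wk(u, d) += ah * (X(i, d) - Wk(u, d));
      }
    }
  }
  return Wk;
}
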