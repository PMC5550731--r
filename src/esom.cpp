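#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Online SOM training. Neurons are row-major: unit u (0-based) sits at
// (u / cols, u % cols). BMU ties resolve to the smallest unit index, i.e.
// lexicographic (row, col). The neighborhood kernel is Gaussian in toroidal
// grid distance; at radius 0 only the BMU itself is updated.
// [[Rcpp::export]]
NumericMatrix esom_train_cpp(NumericMatrix weights, NumericMatrix data,
                             IntegerMatrix orders, int rows, int cols,
                             bool toroid, NumericVector radii,
                             NumericVector rates) {
  const int n_units = weights.nrow();
  const int d = weights.ncol();
  const int n = data.nrow();
  const int epochs = orders.ncol();
  NumericMatrix w = clone(weights);

  for (int e = 0; e < epochs; ++e) {
    const double r = radii[e];
    const double a = rates[e];
    const double denom = (r > 0.0) ? 2.0 * r * r : 0.0;
    for (int s = 0; s < n; ++s) {
      const int i = orders(s, e) - 1; // R indices are 1-based
      // best matching unit
      int bmu = 0;
      double best = R_PosInf;
      for (int u = 0; u < n_units; ++u) {
        double d2 = 0.0;
        for (int j = 0; j < d; ++j) {
          const double diff = w(u, j) - data(i, j);
          d2 += diff * diff;
        }
        if (d2 < best) { best = d2; bmu = u; }
      }
      const int br = bmu / cols, bc = bmu % cols;
      for (int u = 0; u < n_units; ++u) {
        double dr = std::abs(u / cols - br);
        double dc = std::abs(u % cols - bc);
        if (toroid) {
          if (rows - dr < dr) dr = rows - dr;
          if (cols - dc < dc) dc = cols - dc;
        }
        const double g2 = dr * dr + dc * dc;
        double h;
        if (denom > 0.0) {
          h = std::exp(-g2 / denom);
        } else {
          h = (g2 == 0.0) ? 1.0 : 0.0;
        }
        if (h < 1e-12) continue;
        const double ah = a * h;
        for (int j = 0; j < d; ++j) {
          w(u, j) += ah * (data(i, j) - w(u, j));
        }
      }
    }
    for (int u = 0; u < n_units; ++u) {
      for (int j = 0; j < d; ++j) {
        if (!std::isfinite(w(u, j))) {
          stop("non-finite weight during epoch %d", e + 1);
        }
      }
    }
  }
  return w;
}
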