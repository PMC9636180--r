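#include <Rcpp.h>
using namespace Rcpp;

// Online self-organizing-map training: cells presented one at a time in the
// caller-supplied order; the best-matching node and its grid neighbourhood
// (Gaussian kernel on grid coordinates) move towards each cell. Learning
// rate and neighbourhood radius decay per presentation step.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(const NumericMatrix& x, NumericMatrix codes,
                            const IntegerVector& order,
                            const NumericVector& alphas,
                            const NumericVector& radii,
                            const NumericMatrix& grid_xy) {
  const int n_nodes = codes.nrow(), d = codes.ncol(), steps = order.size();
  std::vector<double> gd2(n_nodes * n_nodes);
  for (int a = 0; a < n_nodes; ++a)
    for (int b = 0; b < n_nodes; ++b) {
      double dr = grid_xy(a, 0) - grid_xy(b, 0);
      double dc = grid_xy(a, 1) - grid_xy(b, 1);
      gd2[a * n_nodes + b] = dr * dr + dc * dc;
    }
  for (int s = 0; s < steps; ++s) {
    const int i = order[s] - 1;
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < n_nodes; ++k) {
      double dist = 0.0;
      for (int j = 0; j < d; ++j) {
        double diff = x(i, j) - codes(k, j);
        dist += diff * diff;
      }
      if (dist < best) { best = dist; bmu = k; }
    }
    const double alpha = alphas[s], two_r2 = 2.0 * radii[s] * radii[s];
    for (int k = 0; k < n_nodes; ++k) {
      double h = std::exp(-gd2[bmu * n_nodes + k] / two_r2);
      if (h < 1e-8) continue;
      double ah = alpha * h;
      for (int j = 0; j < d; ++j)
        codes(k, j) += ah * (x(i, j) - codes(k, j));
    }
  }
  return codes;
}
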