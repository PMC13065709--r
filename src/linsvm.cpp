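#include <Rcpp.h>
#include <random>
#include <numeric>

using namespace Rcpp;

// Dual coordinate descent for the L1-loss linear SVM (hinge loss),
//   min_a 0.5 a'Qa - e'a,  0 <= a_i <= C,  Q_ij = y_i y_j x_i'x_j,
// with the bias handled by the caller as an augmented constant feature.
// Deterministic given `seed` (epoch-wise index shuffles use a private
// mt19937, independent of R's RNG).
// [[Rcpp::export]]
List linsvm_dcd(NumericMatrix X, NumericVector y, double C,
                int max_epochs = 1000, double tol = 1e-8, int seed = 1) {
  const int n = X.nrow(), p = X.ncol();
  // row-major copy: the inner loop walks one sample's features contiguously
  std::vector<double> xr(static_cast<size_t>(n) * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j)
      xr[static_cast<size_t>(i) * p + j] = X(i, j);

  std::vector<double> w(p, 0.0), alpha(n, 0.0), qii(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double* xi = &xr[static_cast<size_t>(i) * p];
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);

  int epoch = 0;
  for (; epoch < max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = idx[t];
      if (qii[i] <= 0.0) continue;
      const double* xi = &xr[static_cast<size_t>(i) * p];
      double g = 0.0;
      for (int j = 0; j < p; ++j) g += w[j] * xi[j];
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= C) pg = std::max(g, 0.0);
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-14) {
        const double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double d = (a_new - a_old) * y[i];
        for (int j = 0; j < p; ++j) w[j] += d * xi[j];
      }
    }
    if (max_pg < tol) break;
  }

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch + 1);
}
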