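#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Binary soft-margin C-SVC solver on a precomputed kernel matrix.
// Dual: min_a 0.5 a'Qa - e'a, 0 <= a_i <= C, y'a = 0, with Q_ij = y_i y_j K_ij.
// Working-set selection is the maximal violating pair (first-order rule);
// stopping criterion m(a) - M(a) < eps as in standard SMO solvers.
// Returns alpha, the intercept b (decision f(x) = sum_i a_i y_i K(x_i, x) + b),
// and the iteration count.
// [[Rcpp::export]]
List smo_train(NumericMatrix K, IntegerVector y, double C,
               double eps = 1e-3, int max_iter = 100000) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("label length mismatch");
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double tau = 1e-12;

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // select i: max over I_up of -y_t G_t;  j: min over I_low of -y_t G_t
    int i = -1, j = -1;
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      const bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      const double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    const double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
      if (quad <= 0) quad = tau;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = tau;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // intercept from the free support vectors (0 < alpha < C); fall back to
  // the midpoint of the feasibility bounds when none are free.
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > tau && alpha[t] < C - tau) { b += -y[t] * G[t]; ++nfree; }
  }
  if (nfree > 0) {
    b /= nfree;
  } else {
    double ub = std::numeric_limits<double>::infinity();
    double lb = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      const bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (up && v > lb) lb = v;
      if (low && v < ub) ub = v;
    }
    b = (lb + ub) / 2.0;
    if (!std::isfinite(b)) b = 0.0;
  }
  return List::create(_["alpha"] = alpha, _["b"] = b, _["iterations"] = iter);
}
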