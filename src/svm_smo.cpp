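#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Binary soft-margin SVM dual solved by SMO with maximal-violating-pair
// working-set selection (first-order heuristic):
//   min_a 0.5 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,
// with Q_ij = y_i y_j K(x_i, x_j) and an RBF kernel
// K(u, v) = exp(-gamma ||u - v||^2). Returns alpha and the intercept rho so
// that the decision function is f(x) = sum_i y_i a_i K(x_i, x) - rho.

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  const int d = X.ncol();
  for (int k = 0; k < d; ++k) {
    const double dif = X(i, k) - X(j, k);
    s += dif * dif;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List smo_train_cpp(NumericMatrix X, IntegerVector y, double C, double gamma,
                   double eps = 1e-3, int max_iter = 200000) {
  const int n = X.nrow();
  if (y.size() != n) stop("X and y sizes disagree");

  // dense kernel; training sets here are a few hundred rows
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      K[(size_t)i * n + j] = K[(size_t)j * n + i] = rbf(X, i, j, gamma);

  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G = Q a - e
  const double tau = 1e-12;
  int iter = 0;
  double m_up = 0, m_low = 0;
  while (iter++ < max_iter) {
    // select maximal violating pair
    int i = -1, j = -1;
    m_up = -INFINITY; m_low = INFINITY;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool in_up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      const bool in_low = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low <= eps) break;

    double a = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
               2.0 * y[i] * y[j] * K[(size_t)i * n + j];
    if (a <= 0) a = tau;
    const double delta = (m_up - m_low) / a;

    const double sum = y[i] * alpha[i] + y[j] * alpha[j];
    double ai = alpha[i] + y[i] * delta;
    ai = std::min(std::max(ai, 0.0), C);
    double aj = y[j] * (sum - y[i] * ai);
    aj = std::min(std::max(aj, 0.0), C);
    ai = y[i] * (sum - y[j] * aj);
    ai = std::min(std::max(ai, 0.0), C);

    const double di = ai - alpha[i], dj = aj - alpha[j];
    if (std::fabs(di) < tau && std::fabs(dj) < tau) break;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K[(size_t)i * n + t] * di +
                      y[j] * K[(size_t)j * n + t] * dj);
    }
    alpha[i] = ai;
    alpha[j] = aj;
  }
  const double rho = -(m_up + m_low) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iter"] = iter);
}

// Decision values f(x) = sum_i y_i a_i K(x_i, x) - rho for new rows.
// [[Rcpp::export]]
NumericVector svm_decision_cpp(NumericMatrix Xtrain, IntegerVector y,
                               NumericVector alpha, double rho, double gamma,
                               NumericMatrix Xnew) {
  const int n = Xtrain.nrow(), m = Xnew.nrow(), d = Xtrain.ncol();
  if (Xnew.ncol() != d) stop("feature dimension mismatch");
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    double f = -rho;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] == 0.0) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double dif = Xtrain(i, k) - Xnew(t, k);
        s += dif * dif;
      }
      f += y[i] * alpha[i] * std::exp(-gamma * s);
    }
    out[t] = f;
  }
  return out;
}
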