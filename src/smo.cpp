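// Sequential minimal optimization for a binary C-SVC with RBF kernel.
// Working-set selection is the first-order maximal-violating-pair rule;
// the dual gradient is maintained incrementally so each iteration is O(n).
// Deterministic: no randomness anywhere.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double rbf_kernel(const double* xi, const double* xj,
                                int d, int n, double gamma) {
  // column-major R matrix: element (row i, col c) at [c*n + i]
  double s = 0.0;
  for (int c = 0; c < d; ++c) {
    double diff = xi[c * n] - xj[c * n];
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export(name = ".smo_fit")]]
List smo_fit(NumericMatrix X, NumericVector y, double C, double gamma,
             double eps = 1e-3, int max_iter = 0) {
  const int n = X.nrow(), d = X.ncol();
  if (y.size() != n) stop("y length mismatch");
  if (max_iter <= 0) max_iter = std::max(10000000 / std::max(n, 1), 200 * n);

  // full kernel matrix (problems here are small: n in the hundreds)
  std::vector<double> K((size_t)n * n);
  const double* xp = X.begin();
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double k = rbf_kernel(xp + i, xp + j, d, n, gamma);
      K[(size_t)i * n + j] = k;
      K[(size_t)j * n + i] = k;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);  // G = grad of dual obj
  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  for (; iter < max_iter; ++iter) {
    // maximal violating pair
    int i = -1, j = -1;
    m_up = -HUGE_VAL; m_low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool in_up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool in_low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;

    double eta = K[(size_t)i * n + i] + K[(size_t)j * n + j]
               - 2.0 * K[(size_t)i * n + j];
    if (eta <= 0) eta = 1e-12;
    // E_t = f_hat(x_t) - y_t = y_t * G_t  (bias cancels in the difference)
    double Ei = y[i] * G[i], Ej = y[j] * G[j];
    double s = y[i] * y[j];
    double L, H;
    if (s < 0) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    double aj_new = alpha[j] + y[j] * (Ei - Ej) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double d_aj = aj_new - alpha[j];
    if (std::fabs(d_aj) < 1e-14) break;  // numerically stuck
    double ai_new = alpha[i] - s * d_aj;
    double d_ai = ai_new - alpha[i];
    alpha[i] = ai_new;
    alpha[j] = aj_new;
    // G_t += Q_ti dai + Q_tj daj, Q_tl = y_t y_l K_tl
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K[(size_t)i * n + t] * d_ai +
                      y[j] * K[(size_t)j * n + t] * d_aj);
    }
  }
  double b = (m_up > -HUGE_VAL && m_low < HUGE_VAL) ? (m_up + m_low) / 2.0 : 0.0;

  std::vector<int> sv;
  for (int t = 0; t < n; ++t) if (alpha[t] > 1e-12) sv.push_back(t);
  NumericVector coef(sv.size());
  IntegerVector sv_index(sv.size());
  for (size_t t = 0; t < sv.size(); ++t) {
    sv_index[t] = sv[t] + 1;                 // 1-based for R
    coef[t] = alpha[sv[t]] * y[sv[t]];
  }
  return List::create(_["sv_index"] = sv_index, _["coef"] = coef,
                      _["b"] = b, _["iter"] = iter);
}

// [[Rcpp::export(name = ".smo_decision")]]
NumericVector smo_decision(NumericMatrix SV, NumericVector coef, double b,
                           double gamma, NumericMatrix Xnew) {
  const int nsv = SV.nrow(), d = SV.ncol(), m = Xnew.nrow();
  if (Xnew.ncol() != d) stop("feature count mismatch");
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double f = b;
    for (int s = 0; s < nsv; ++s) {
      double acc = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = SV(s, c) - Xnew(q, c);
        acc += diff * diff;
      }
      f += coef[s] * std::exp(-gamma * acc);
    }
    out[q] = f;
  }
  return out;
}
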