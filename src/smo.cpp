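// Sequential minimal optimisation for a C-SVC with RBF kernel.
// Working-set selection by maximal violating pair; dense precomputed
// kernel (problem sizes here are a few thousand rows at most).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  const int d = X.ncol();
  for (int k = 0; k < d; ++k) {
    const double diff = X(i, k) - X(j, k);
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

// Solve: min_a 1/2 a'Qa - e'a,  0 <= a_i <= C_i,  y'a = 0,
// with Q_ij = y_i y_j K_ij. Returns alpha, rho (so that the decision
// function is sum_i alpha_i y_i K(x_i, x) + rho), iterations and the final
// KKT violation gap.
// [[Rcpp::export(name = ".smo_fit")]]
List smo_fit(NumericMatrix X, NumericVector y, double C_pos, double C_neg,
             double gamma, double eps = 1e-3, int max_iter = 1000000) {
  const int n = X.nrow();
  if (n < 2) stop("need at least two training rows");

  // dense kernel
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const double v = rbf(X, i, j, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0), C(n);
  for (int i = 0; i < n; ++i) C[i] = (y[i] > 0) ? C_pos : C_neg;

  int iter = 0;
  double gap = R_PosInf;
  while (iter < max_iter) {
    // maximal violating pair over I_up / I_low
    int ii = -1, jj = -1;
    double m_up = -R_PosInf, m_low = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool in_up = (y[t] > 0 && alpha[t] < C[t]) || (y[t] < 0 && alpha[t] > 0);
      const bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C[t]);
      if (in_up && v > m_up) { m_up = v; ii = t; }
      if (in_low && v < m_low) { m_low = v; jj = t; }
    }
    gap = m_up - m_low;
    if (ii < 0 || jj < 0 || gap <= eps) break;

    // optimal step for the pair, then clip to the box
    double quad = K[(size_t)ii * n + ii] + K[(size_t)jj * n + jj]
                - 2.0 * K[(size_t)ii * n + jj];
    if (quad <= 0) quad = 1e-12;
    double t_step = -(y[ii] * G[ii] - y[jj] * G[jj]) / quad;

    double t_min, t_max;
    if (y[ii] > 0) { t_min = -alpha[ii]; t_max = C[ii] - alpha[ii]; }
    else           { t_min = alpha[ii] - C[ii]; t_max = alpha[ii]; }
    if (y[jj] > 0) { t_min = std::max(t_min, alpha[jj] - C[jj]); t_max = std::min(t_max, alpha[jj]); }
    else           { t_min = std::max(t_min, -alpha[jj]); t_max = std::min(t_max, C[jj] - alpha[jj]); }
    if (t_step < t_min) t_step = t_min;
    if (t_step > t_max) t_step = t_max;
    if (t_step == 0.0) break;

    const double d_i = y[ii] * t_step;   // change in alpha_i
    const double d_j = -y[jj] * t_step;  // change in alpha_j
    alpha[ii] += d_i;
    alpha[jj] += d_j;
    for (int t2 = 0; t2 < n; ++t2) {
      G[t2] += y[t2] * y[ii] * K[(size_t)ii * n + t2] * d_i
             + y[t2] * y[jj] * K[(size_t)jj * n + t2] * d_j;
    }
    ++iter;
  }

  // intercept: average of -y G over free vectors, else the gap midpoint
  double rho;
  {
    double sum = 0.0;
    int nfree = 0;
    double m_up = -R_PosInf, m_low = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool in_up = (y[t] > 0 && alpha[t] < C[t]) || (y[t] < 0 && alpha[t] > 0);
      const bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C[t]);
      if (in_up && v > m_up) m_up = v;
      if (in_low && v < m_low) m_low = v;
      if (alpha[t] > 1e-12 && alpha[t] < C[t] - 1e-12) { sum += v; ++nfree; }
    }
    rho = nfree > 0 ? sum / nfree : 0.5 * (m_up + m_low);
  }

  // keep only support vectors
  std::vector<int> sv;
  for (int i = 0; i < n; ++i) if (alpha[i] > 1e-12) sv.push_back(i);
  NumericMatrix SV((int)sv.size(), X.ncol());
  NumericVector coef((int)sv.size());
  for (size_t s = 0; s < sv.size(); ++s) {
    coef[s] = alpha[sv[s]] * y[sv[s]];
    for (int k = 0; k < X.ncol(); ++k) SV(s, k) = X(sv[s], k);
  }

  return List::create(_["sv"] = SV, _["coef"] = coef, _["rho"] = rho,
                      _["iterations"] = iter, _["gap"] = gap,
                      _["converged"] = (gap <= eps));
}

// Decision scores sum_s coef_s K(sv_s, x) + rho for each row of Xnew.
// [[Rcpp::export(name = ".smo_decision")]]
NumericVector smo_decision(NumericMatrix SV, NumericVector coef, double rho,
                           double gamma, NumericMatrix Xnew) {
  const int m = Xnew.nrow(), ns = SV.nrow(), d = SV.ncol();
  if (Xnew.ncol() != d) stop("feature dimension mismatch");
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double acc = rho;
    for (int s = 0; s < ns; ++s) {
      double dist = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = Xnew(i, k) - SV(s, k);
        dist += diff * diff;
      }
      acc += coef[s] * std::exp(-gamma * dist);
    }
    out[i] = acc;
  }
  return out;
}
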