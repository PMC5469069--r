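// C-support vector classifier with an RBF kernel, trained by sequential
// minimal optimisation (Platt's SMO with the |E1-E2| second-choice
// heuristic).  Deterministic: no randomised scan order.  Suitable for the
// dataset sizes this package trains on (hundreds to a few thousand rows);
// the full kernel matrix is held in memory.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SMO {
  int n;
  double C, tol, eps;
  const std::vector<double>& K;  // n x n kernel, column-major
  const std::vector<double>& y;  // +1 / -1
  std::vector<double> alpha, E;
  double b;
  long steps, max_steps;

  SMO(int n_, double C_, double tol_, const std::vector<double>& K_,
      const std::vector<double>& y_, long max_steps_)
      : n(n_), C(C_), tol(tol_), eps(1e-12), K(K_), y(y_),
        alpha(n_, 0.0), E(n_), b(0.0), steps(0), max_steps(max_steps_) {
    for (int i = 0; i < n; ++i) E[i] = -y[i];  // u = 0 initially
  }

  inline double k(int i, int j) const { return K[(size_t)j * n + i]; }

  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2], s = y1 * y2;
    double E1 = E[i1], E2 = E[i2];
    double L, H;
    if (y1 != y2) {
      L = std::max(0.0, a2 - a1);
      H = std::min(C, C + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - C);
      H = std::min(C, a1 + a2);
    }
    if (L >= H) return false;
    double k11 = k(i1, i1), k12 = k(i1, i2), k22 = k(i2, i2);
    double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > 0) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L;
      else if (a2new > H) a2new = H;
    } else {
      // degenerate kernel direction: evaluate objective at the clip ends
      double f1 = y1 * (E1 + b) - a1 * k11 - s * a2 * k12;
      double f2 = y2 * (E2 + b) - s * a1 * k12 - a2 * k22;
      double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      double Lobj = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                    0.5 * L * L * k22 + s * L * L1 * k12;
      double Hobj = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                    0.5 * H * H * k22 + s * H * H1 * k12;
      if (Lobj < Hobj - eps) a2new = L;
      else if (Lobj > Hobj + eps) a2new = H;
      else a2new = a2;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    double a1new = a1 + s * (a2 - a2new);

    double b1 = E1 + y1 * (a1new - a1) * k11 + y2 * (a2new - a2) * k12 + b;
    double b2 = E2 + y1 * (a1new - a1) * k12 + y2 * (a2new - a2) * k22 + b;
    double bnew;
    if (a1new > 0 && a1new < C) bnew = b1;
    else if (a2new > 0 && a2new < C) bnew = b2;
    else bnew = (b1 + b2) / 2.0;

    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2), db = bnew - b;
    for (int j = 0; j < n; ++j)
      E[j] += d1 * k(i1, j) + d2 * k(i2, j) - db;
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    b = bnew;
    ++steps;
    return true;
  }

  bool examine(int i2) {
    double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    double r2 = E2 * y2;
    if (!((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0))) return false;

    // heuristic 1: maximise |E1 - E2| over non-bound alphas
    int best = -1;
    double bestgap = -1.0;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] > 0 && alpha[i] < C) {
        double gap = std::fabs(E[i] - E2);
        if (gap > bestgap) { bestgap = gap; best = i; }
      }
    }
    if (best >= 0 && take_step(best, i2)) return true;
    // heuristic 2: all non-bound, then all, in index order (deterministic)
    for (int i = 0; i < n; ++i)
      if (alpha[i] > 0 && alpha[i] < C && take_step(i, i2)) return true;
    for (int i = 0; i < n; ++i)
      if (!(alpha[i] > 0 && alpha[i] < C) && take_step(i, i2)) return true;
    return false;
  }

  void solve() {
    int num_changed = 0;
    bool examine_all = true;
    while ((num_changed > 0 || examine_all) && steps < max_steps) {
      num_changed = 0;
      for (int i = 0; i < n; ++i) {
        if (examine_all || (alpha[i] > 0 && alpha[i] < C))
          if (examine(i)) ++num_changed;
        if (steps >= max_steps) break;
      }
      if (examine_all) examine_all = false;
      else if (num_changed == 0) examine_all = true;
    }
  }
};

std::vector<double> rbf_kernel(const NumericMatrix& A, const NumericMatrix& B,
                               double gamma) {
  int na = A.nrow(), nb = B.nrow(), p = A.ncol();
  std::vector<double> K((size_t)na * nb);
  for (int j = 0; j < nb; ++j)
    for (int i = 0; i < na; ++i) {
      double d2 = 0.0;
      for (int c = 0; c < p; ++c) {
        double d = A(i, c) - B(j, c);
        d2 += d * d;
      }
      K[(size_t)j * na + i] = std::exp(-gamma * d2);
    }
  return K;
}

}  // namespace

// [[Rcpp::export(name = ".svm_fit_cpp")]]
List svm_fit_cpp(NumericMatrix X, NumericVector y, double C, double gamma,
                 double tol, double max_steps_per_row) {
  int n = X.nrow();
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> K = rbf_kernel(X, X, gamma);
  SMO smo(n, C, tol, K, yv, (long)(max_steps_per_row * n));
  smo.solve();
  NumericVector alpha(smo.alpha.begin(), smo.alpha.end());
  // training decision values u_i = E_i + y_i
  NumericVector decision(n);
  for (int i = 0; i < n; ++i) decision[i] = smo.E[i] + yv[i];
  return List::create(_["alpha"] = alpha, _["b"] = smo.b,
                      _["decision"] = decision, _["steps"] = (double)smo.steps);
}

// [[Rcpp::export(name = ".svm_decision_cpp")]]
NumericVector svm_decision_cpp(NumericMatrix Xtrain, NumericVector y,
                               NumericVector alpha, double b, double gamma,
                               NumericMatrix Xnew) {
  int n = Xtrain.nrow(), m = Xnew.nrow();
  std::vector<double> K = rbf_kernel(Xtrain, Xnew, gamma);
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double u = 0.0;
    for (int i = 0; i < n; ++i)
      if (alpha[i] > 0)
        u += alpha[i] * y[i] * K[(size_t)j * n + i];
    out[j] = u - b;
  }
  return out;
}
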