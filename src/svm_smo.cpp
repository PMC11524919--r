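#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for linear C-SVC (hinge loss, L2 margin,
// unregularized intercept). Dual: min 1/2 a'Qa - e'a, 0 <= a <= C, y'a = 0,
// Q_ij = y_i y_j x_i.x_j.
// Small-n use (LOOCV on ~10^2 rows); the kernel matrix is formed densely.
// Working-set selection is second order (libsvm WSS2).

namespace {

struct SmoFit {
  std::vector<double> alpha;
  double rho;        // decision f(x) = w.x - rho
  int iter;
  double obj;        // dual objective at the solution
};

SmoFit smo_solve(const double* X, int n, int p, const int* y, double C,
                 double tol, int max_iter,
                 const double* alpha_init = nullptr) {
  std::vector<double> K(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += X[i + n * k] * X[j + n * k];
      K[i + static_cast<size_t>(n) * j] = s;
      K[j + static_cast<size_t>(n) * i] = s;
    }
  }
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  if (alpha_init) {
    // warm start: clip to the box, rebalance the equality constraint by
    // scaling down the heavier class side, then rebuild the gradient
    double s_pos = 0.0, s_neg = 0.0;
    for (int t = 0; t < n; ++t) {
      alpha[t] = std::min(std::max(alpha_init[t], 0.0), C);
      if (y[t] == 1) s_pos += alpha[t]; else s_neg += alpha[t];
    }
    if (s_pos > 0 && s_neg > 0) {
      double f_pos = s_pos > s_neg ? s_neg / s_pos : 1.0;
      double f_neg = s_neg > s_pos ? s_pos / s_neg : 1.0;
      for (int t = 0; t < n; ++t) alpha[t] *= (y[t] == 1 ? f_pos : f_neg);
      for (int t = 0; t < n; ++t) {
        double g = -1.0;
        for (int s = 0; s < n; ++s) {
          if (alpha[s] != 0.0)
            g += y[t] * y[s] * K[t + static_cast<size_t>(n) * s] * alpha[s];
        }
        G[t] = g;
      }
    } else {
      std::fill(alpha.begin(), alpha.end(), 0.0);
    }
  }
  const double TAU = 1e-12;
  int it = 0;
  for (; it < max_iter; ++it) {
    // second-order working-set selection (libsvm WSS2): i maximizes the
    // KKT violation over I_up; j minimizes the one-step objective decrease
    // over violating members of I_low
    int i = -1, j = -1;
    double Gmax = -HUGE_VAL, Gmin = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
    }
    if (i >= 0) {
      double Kii = K[i + static_cast<size_t>(n) * i];
      double best = HUGE_VAL;
      for (int t = 0; t < n; ++t) {
        bool lo = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
        if (!lo) continue;
        double v = -y[t] * G[t];
        if (v < Gmin) Gmin = v;
        double b = Gmax - v;
        if (b > 0) {
          // curvature along the feasible pair direction is label-free
          double a = Kii + K[t + static_cast<size_t>(n) * t] -
            2.0 * K[i + static_cast<size_t>(n) * t];
          if (a <= 0) a = TAU;
          double dec = -(b * b) / a;
          if (dec < best) { best = dec; j = t; }
        }
      }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < tol) break;

    double Kii = K[i + static_cast<size_t>(n) * i];
    double Kjj = K[j + static_cast<size_t>(n) * j];
    double Kij = K[i + static_cast<size_t>(n) * j];
    double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
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
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        else if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        else if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t) {
      double Qti = y[t] * y[i] * K[t + static_cast<size_t>(n) * i];
      double Qtj = y[t] * y[j] * K[t + static_cast<size_t>(n) * j];
      G[t] += Qti * dai + Qtj * daj;
    }
  }
  // rho: average y*G over free SVs, else midpoint of the violating bounds
  double rho;
  {
    double sum_free = 0.0;
    int n_free = 0;
    double ub = HUGE_VAL, lb = -HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double yG = y[t] * G[t];
      bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool lo = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      if (alpha[t] > 0 && alpha[t] < C) { sum_free += yG; ++n_free; }
      if (up) ub = std::min(ub, yG);
      if (lo) lb = std::max(lb, yG);
    }
    rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;
  }
  // G = Qa - e, so 1/2 a'Qa - e'a = sum_t a_t (G_t - 1) / 2
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += 0.5 * alpha[t] * (G[t] - 1.0);
  SmoFit out;
  out.alpha = std::move(alpha);
  out.rho = rho;
  out.iter = it;
  out.obj = obj;
  return out;
}

void weights_from_alpha(const double* X, int n, int p, const int* y,
                        const std::vector<double>& alpha, double* w) {
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int t = 0; t < n; ++t) s += alpha[t] * y[t] * X[t + n * k];
    w[k] = s;
  }
}

} // namespace

// [[Rcpp::export(name = ".smo_fit")]]
List smo_fit_cpp(NumericMatrix X, IntegerVector y, double cost,
                 double tol = 1e-3, int max_iter = 200000) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  bool pos = false, neg = false;
  for (int t = 0; t < n; ++t) {
    if (y[t] == 1) pos = true;
    else if (y[t] == -1) neg = true;
    else stop("y must be coded +1/-1");
  }
  if (!pos || !neg) stop("both classes must be present to fit an SVM");
  SmoFit fit = smo_solve(X.begin(), n, p, y.begin(), cost, tol, max_iter);
  NumericVector w(p);
  weights_from_alpha(X.begin(), n, p, y.begin(), fit.alpha, w.begin());
  return List::create(_["weights"] = w, _["intercept"] = -fit.rho,
                      _["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["iterations"] = fit.iter, _["dual_objective"] = fit.obj);
}

// Out-of-fold decision values under k-fold CV with per-fold standardization.
// fold_id is 0-based; LOOCV is fold_id = 0:(n-1). Columns with zero training
// spread are centred and left unscaled.
// [[Rcpp::export(name = ".smo_cv_decisions")]]
NumericVector smo_cv_decisions_cpp(NumericMatrix X, IntegerVector y,
                                   double cost, IntegerVector fold_id,
                                   bool standardize = true,
                                   double tol = 1e-3, int max_iter = 200000) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n || fold_id.size() != n) stop("y/fold_id length mismatch");
  int n_fold = 0;
  for (int t = 0; t < n; ++t) n_fold = std::max(n_fold, fold_id[t] + 1);
  NumericVector out(n);
  std::vector<double> Xtr, w(p), mu(p), sc(p);
  std::vector<int> ytr, test_rows;
  // consecutive folds differ in few rows, so each fold is warm-started
  // from the previous fold's dual solution (projected back to feasibility)
  std::vector<double> warm(n, 0.0), a0;
  bool have_warm = false;
  for (int f = 0; f < n_fold; ++f) {
    int ntr = 0;
    test_rows.clear();
    for (int t = 0; t < n; ++t) {
      if (fold_id[t] == f) test_rows.push_back(t); else ++ntr;
    }
    if (test_rows.empty()) continue;
    if (ntr < 2) stop("training fold too small");
    Xtr.assign(static_cast<size_t>(ntr) * p, 0.0);
    ytr.assign(ntr, 0);
    int r = 0;
    bool pos = false, neg = false;
    for (int t = 0; t < n; ++t) {
      if (fold_id[t] == f) continue;
      for (int k = 0; k < p; ++k) Xtr[r + ntr * k] = X(t, k);
      ytr[r] = y[t];
      if (y[t] == 1) pos = true; else neg = true;
      ++r;
    }
    if (!pos || !neg)
      stop("a training fold lost one class entirely; cannot cross-validate");
    for (int k = 0; k < p; ++k) {
      double m = 0.0;
      for (int t = 0; t < ntr; ++t) m += Xtr[t + ntr * k];
      m /= ntr;
      double v = 0.0;
      for (int t = 0; t < ntr; ++t) {
        double d = Xtr[t + ntr * k] - m;
        v += d * d;
      }
      double s = ntr > 1 ? std::sqrt(v / (ntr - 1)) : 0.0;
      mu[k] = standardize ? m : 0.0;
      sc[k] = (standardize && s > 0) ? s : 1.0;
      if (standardize)
        for (int t = 0; t < ntr; ++t)
          Xtr[t + ntr * k] = (Xtr[t + ntr * k] - mu[k]) / sc[k];
    }
    const double* init = nullptr;
    if (have_warm) {
      a0.assign(ntr, 0.0);
      int rr = 0;
      for (int t = 0; t < n; ++t) {
        if (fold_id[t] == f) continue;
        a0[rr++] = warm[t];
      }
      init = a0.data();
    }
    SmoFit fit = smo_solve(Xtr.data(), ntr, p, ytr.data(), cost, tol,
                           max_iter, init);
    {
      int rr = 0;
      for (int t = 0; t < n; ++t) {
        if (fold_id[t] == f) continue;
        warm[t] = fit.alpha[rr++];
      }
      have_warm = true;
    }
    weights_from_alpha(Xtr.data(), ntr, p, ytr.data(), fit.alpha, w.data());
    for (int ti : test_rows) {
      double d = -fit.rho;
      for (int k = 0; k < p; ++k) d += w[k] * ((X(ti, k) - mu[k]) / sc[k]);
      out[ti] = d;
    }
  }
  return out;
}
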