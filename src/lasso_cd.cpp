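#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// L1-penalized logistic regression over binary indicator columns, solved by
// iteratively reweighted least squares with cyclic coordinate descent on the
// weighted subproblem (an active-set strategy with full-sweep verification).
// The indicator columns are stored sparsely as row-index lists, which is
// exact because entries are 0/1. The intercept is never penalized.
//
// Objective: (1/n) * sum_i [log(1 + exp(eta_i)) - y_i * eta_i] + lambda * ||beta||_1

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static double objective(const std::vector<double> &eta, const NumericVector &y,
                        const std::vector<double> &beta, double lambda, int n) {
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = eta[i];
    double l1p = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    nll += l1p - y[i] * e;
  }
  double pen = 0.0;
  for (size_t j = 0; j < beta.size(); ++j) pen += std::fabs(beta[j]);
  return nll / n + lambda * pen;
}

// [[Rcpp::export(name = ".lasso_logistic_path_cpp")]]
List lasso_logistic_path_cpp(IntegerMatrix X, NumericVector y,
                             NumericVector lambda, double tol, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  if (y.size() != n) stop("y length must match nrow(X)");

  // sparse binary columns
  std::vector<std::vector<int>> idx(p);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      int v = X(i, j);
      if (v == 1) idx[j].push_back(i);
      else if (v != 0) stop("rule-indicator matrix must be binary 0/1");
    }
  }

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  if (ybar <= 0.0 || ybar >= 1.0) stop("outcome has a single class");

  std::vector<double> beta(p, 0.0);
  double b0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> eta(n, b0), w(n), r(n);

  NumericMatrix B(p, L);
  NumericVector B0(L), OBJ(L);
  IntegerVector SWEEPS(L);

  const double wmin = 1e-5;

  for (int l = 0; l < L; ++l) {
    double lam = lambda[l];
    int sweeps_used = 0;
    double obj_prev = objective(eta, y, beta, lam, n);
    for (int outer = 0; outer < 25; ++outer) {
      // working response / weights at current eta
      double max_outer_change = 0.0;
      std::vector<double> beta_before = beta;
      double b0_before = b0;
      for (int i = 0; i < n; ++i) {
        double pi = 1.0 / (1.0 + std::exp(-eta[i]));
        double wi = pi * (1.0 - pi);
        if (wi < wmin) wi = wmin;
        w[i] = wi;
        r[i] = (y[i] - pi) / wi;  // residual of working response about eta
      }
      double sw = 0.0;
      for (int i = 0; i < n; ++i) sw += w[i];

      // coordinate descent on the weighted penalized LS subproblem
      bool converged_inner = false;
      while (!converged_inner && sweeps_used < max_sweeps) {
        // full sweep
        double d_full = 0.0;
        {
          // intercept
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += w[i] * r[i];
          double d = num / sw;
          if (d != 0.0) {
            b0 += d;
            for (int i = 0; i < n; ++i) r[i] -= d;
            d_full = std::max(d_full, std::fabs(d));
          }
          for (int j = 0; j < p; ++j) {
            double xwr = 0.0, xwx = 0.0;
            for (int i : idx[j]) { xwr += w[i] * r[i]; xwx += w[i]; }
            if (xwx <= 0.0) continue;
            double bj = beta[j];
            double znum = xwr / n + (xwx / n) * bj;
            double bnew = soft(znum, lam) / (xwx / n);
            double d2 = bnew - bj;
            if (d2 != 0.0) {
              beta[j] = bnew;
              for (int i : idx[j]) r[i] -= d2;
              d_full = std::max(d_full, std::fabs(d2));
            }
          }
        }
        ++sweeps_used;
        if (d_full < tol) { converged_inner = true; break; }
        // active-set sweeps over nonzero coefficients
        std::vector<int> act;
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) act.push_back(j);
        while (sweeps_used < max_sweeps) {
          double d_act = 0.0;
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += w[i] * r[i];
          double d = num / sw;
          if (d != 0.0) {
            b0 += d;
            for (int i = 0; i < n; ++i) r[i] -= d;
            d_act = std::max(d_act, std::fabs(d));
          }
          for (int j : act) {
            double xwr = 0.0, xwx = 0.0;
            for (int i : idx[j]) { xwr += w[i] * r[i]; xwx += w[i]; }
            if (xwx <= 0.0) continue;
            double bj = beta[j];
            double znum = xwr / n + (xwx / n) * bj;
            double bnew = soft(znum, lam) / (xwx / n);
            double d2 = bnew - bj;
            if (d2 != 0.0) {
              beta[j] = bnew;
              for (int i : idx[j]) r[i] -= d2;
              d_act = std::max(d_act, std::fabs(d2));
            }
          }
          ++sweeps_used;
          if (d_act < tol) break;
        }
      }

      // refresh eta from the linear predictor
      for (int i = 0; i < n; ++i) eta[i] = b0;
      for (int j = 0; j < p; ++j) {
        if (beta[j] != 0.0) for (int i : idx[j]) eta[i] += beta[j];
      }
      for (size_t j = 0; j < beta.size(); ++j) {
        max_outer_change = std::max(max_outer_change, std::fabs(beta[j] - beta_before[j]));
      }
      max_outer_change = std::max(max_outer_change, std::fabs(b0 - b0_before));
      if (max_outer_change < tol) break;
      // quadratic approximation stalled: objective no longer moving
      double obj_now = objective(eta, y, beta, lam, n);
      if (obj_prev - obj_now < 1e-9 * (std::fabs(obj_prev) + 1.0)) break;
      obj_prev = obj_now;
      if (sweeps_used >= max_sweeps) break;
    }

    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
    B0[l] = b0;
    OBJ[l] = objective(eta, y, beta, lam, n);
    SWEEPS[l] = sweeps_used;
  }

  return List::create(_["beta"] = B, _["intercept"] = B0,
                      _["objective"] = OBJ, _["sweeps"] = SWEEPS);
}
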