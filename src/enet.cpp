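#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Elastic-net penalized logistic regression along a descending lambda path.
//
// Minimizes (1/n) sum_i [log(1+exp(eta_i)) - y_i eta_i]
//           + lambda * (alpha ||beta||_1 + (1-alpha)/2 ||beta||_2^2)
// with eta = b0 + X beta, intercept unpenalized, X assumed standardized.
// Outer loop: iteratively reweighted quadratic approximation (weights
// p(1-p), working response); inner loop: cyclic coordinate descent with
// soft-thresholding, active-set cycling and warm starts along the path.
//
// [[Rcpp::export]]
List cpp_enet_path(const NumericMatrix& X, const NumericVector& y,
                   double alpha, const NumericVector& lambdas,
                   double tol, int max_sweeps,
                   NumericVector init_beta, double init_b0, bool use_init) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  const double wmin = 1e-5, etacap = 30.0;
  const double* px = REAL(X);
  const double* py = REAL(y);

  std::vector<double> beta(p, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += py[i];
  ybar /= n;
  double b0 = std::log(ybar / (1.0 - ybar));
  if (use_init) {
    b0 = init_b0;
    for (int j = 0; j < p; ++j) beta[j] = init_beta[j];
  }

  std::vector<double> eta(n), w(n), res(n), xv(p);
  std::vector<double> beta_prev(p);
  std::vector<int> active;
  active.reserve(p);

  auto refresh_eta = [&]() {
    for (int i = 0; i < n; ++i) eta[i] = b0;
    for (int j = 0; j < p; ++j) {
      const double bj = beta[j];
      if (bj == 0.0) continue;
      const double* xj = px + (size_t)j * n;
      for (int i = 0; i < n; ++i) eta[i] += xj[i] * bj;
    }
  };
  refresh_eta();

  NumericMatrix beta_out(p, L);
  NumericVector b0_out(L);
  IntegerVector sweeps_out(L);
  LogicalVector conv_out(L);

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    const double l1 = lam * alpha, l2 = lam * (1.0 - alpha);
    int sweeps = 0;
    bool converged = false;

    for (int outer = 0; outer < 100; ++outer) {
      // quadratic approximation at the current linear predictor
      double sw = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = eta[i];
        if (e > etacap) e = etacap; else if (e < -etacap) e = -etacap;
        const double pi = 1.0 / (1.0 + std::exp(-e));
        double wi = pi * (1.0 - pi);
        if (wi < wmin) wi = wmin;
        w[i] = wi;
        sw += wi;
        res[i] = (py[i] - pi) / wi;      // working response minus eta
      }
      for (int j = 0; j < p; ++j) {
        const double* xj = px + (size_t)j * n;
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
        xv[j] = s / n;
      }
      const double b0_start = b0;
      std::copy(beta.begin(), beta.end(), beta_prev.begin());

      // penalized weighted least squares: full sweep, then active-set
      // cycling, then a full sweep to pick up violations; repeat.
      auto update_j = [&](int j) -> double {
        if (xv[j] <= 0.0) { beta[j] = 0.0; return 0.0; }  // constant column
        const double* xj = px + (size_t)j * n;
        double g = 0.0;
        for (int i = 0; i < n; ++i) g += w[i] * xj[i] * res[i];
        g /= n;
        const double bnew = soft(g + xv[j] * beta[j], l1) / (xv[j] + l2);
        const double d = bnew - beta[j];
        if (d != 0.0) {
          beta[j] = bnew;
          for (int i = 0; i < n; ++i) res[i] -= xj[i] * d;
        }
        return std::fabs(d);
      };
      auto update_intercept = [&]() -> double {
        double num = 0.0;
        for (int i = 0; i < n; ++i) num += w[i] * res[i];
        const double d0 = num / sw;
        if (d0 != 0.0) {
          b0 += d0;
          for (int i = 0; i < n; ++i) res[i] -= d0;
        }
        return std::fabs(d0);
      };

      bool wls_done = false;
      while (!wls_done && sweeps < max_sweeps) {
        // full sweep
        double maxd = update_intercept();
        for (int j = 0; j < p; ++j) {
          const double d = update_j(j);
          if (d > maxd) maxd = d;
        }
        ++sweeps;
        if (maxd < tol) { wls_done = true; break; }
        // active-set cycles
        active.clear();
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
        while (sweeps < max_sweeps) {
          double maxda = update_intercept();
          for (int j : active) {
            const double d = update_j(j);
            if (d > maxda) maxda = d;
          }
          ++sweeps;
          if (maxda < tol) break;
        }
      }

      refresh_eta();
      double mstep = std::fabs(b0 - b0_start);
      for (int j = 0; j < p; ++j) {
        const double d = std::fabs(beta[j] - beta_prev[j]);
        if (d > mstep) mstep = d;
      }
      if (wls_done && mstep < 10 * tol) { converged = true; break; }
      if (sweeps >= max_sweeps) break;
    }

    for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
    b0_out[l] = b0;
    sweeps_out[l] = sweeps;
    conv_out[l] = converged;
  }

  return List::create(_["b0"] = b0_out, _["beta"] = beta_out,
                      _["sweeps"] = sweeps_out, _["converged"] = conv_out);
}
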