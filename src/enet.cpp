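#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Penalized negative log-likelihood (minimization objective) at the current
// iterate; only evaluated when tracing, never in the hot loop.
static double penalized_obj(const NumericVector& y,
                            const std::vector<double>& eta,
                            const std::vector<double>& beta,
                            double lambda, double alpha) {
  const int n = y.size();
  const int p = beta.size();
  double nll = 0.0;
  for (int j = 0; j < n; ++j) {
    double e = eta[j];
    double lse = (e > 0.0) ? e + std::log1p(std::exp(-e))
                           : std::log1p(std::exp(e));
    nll += lse - y[j] * e;
  }
  nll /= n;
  double l1 = 0.0, l2 = 0.0;
  for (int i = 0; i < p; ++i) {
    l1 += std::fabs(beta[i]);
    l2 += beta[i] * beta[i];
  }
  return nll + lambda * ((1.0 - alpha) * 0.5 * l2 + alpha * l1);
}

// Elastic-net penalized logistic regression along a decreasing lambda path
// with warm starts. Outer loop: IRLS quadratic approximation (weights
// p(1-p), working response); inner loop: cyclic coordinate descent with an
// active-set strategy (full sweep, then iterate on the nonzero set until
// stable, then a verifying full sweep). X is expected standardized by the
// caller; y must be 0/1 with both classes present. Probabilities are
// clamped to [1e-5, 1 - 1e-5] for weight stability. Convergence uses the
// glmnet-style criterion max_i v_i * (delta beta_i)^2 < tol.
// [[Rcpp::export]]
List enet_logistic_path_cpp(const NumericMatrix& X, const NumericVector& y,
                            const NumericVector& lambda, double alpha,
                            double tol, int max_sweeps, bool trace) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  const double pmin = 1e-5;
  const int max_outer = 250;

  NumericMatrix beta_path(p, L);
  NumericVector beta0_path(L);
  IntegerVector conv(L), sweeps_used(L);
  List obj_trace(L);

  std::vector<double> beta(p, 0.0), eta(n), w(n), z(n), r(n), v(p);

  double ybar = 0.0;
  for (int j = 0; j < n; ++j) ybar += y[j];
  ybar /= n;
  double beta0 = std::log(ybar / (1.0 - ybar));
  std::fill(eta.begin(), eta.end(), beta0);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    const double lam1 = lam * alpha;
    const double lam2 = lam * (1.0 - alpha);
    int sweeps = 0;
    bool outer_conv = false;
    std::vector<double> objs;

    for (int outer = 0; outer < max_outer; ++outer) {
      // quadratic approximation at the current linear predictor
      double wsum = 0.0;
      for (int j = 0; j < n; ++j) {
        double pj = 1.0 / (1.0 + std::exp(-eta[j]));
        // clamp only the weight: the raw residual keeps the fixed point on
        // the true KKT conditions even when probabilities saturate
        double pc = pj;
        if (pc < pmin) pc = pmin;
        else if (pc > 1.0 - pmin) pc = 1.0 - pmin;
        w[j] = pc * (1.0 - pc);
        z[j] = eta[j] + (y[j] - pj) / w[j];
        r[j] = z[j] - eta[j];
        wsum += w[j];
      }
      for (int i = 0; i < p; ++i) {
        const double* xi = X.begin() + (std::size_t)i * n;
        double s = 0.0;
        for (int j = 0; j < n; ++j) s += w[j] * xi[j] * xi[j];
        v[i] = s / n;
      }

      double douter = 0.0;
      bool inner_done = false;
      while (!inner_done && sweeps < max_sweeps) {
        // full sweep over all coordinates plus the intercept
        double dmax = 0.0;
        for (int i = 0; i < p; ++i) {
          const double* xi = X.begin() + (std::size_t)i * n;
          double s = 0.0;
          for (int j = 0; j < n; ++j) s += w[j] * xi[j] * r[j];
          double num = s / n + v[i] * beta[i];
          double bn = soft(num, lam1) / (v[i] + lam2);
          double d = bn - beta[i];
          if (d != 0.0) {
            for (int j = 0; j < n; ++j) r[j] -= d * xi[j];
            beta[i] = bn;
            double m = v[i] * d * d;
            if (m > dmax) dmax = m;
          }
        }
        {
          double s = 0.0;
          for (int j = 0; j < n; ++j) s += w[j] * r[j];
          double d0 = s / wsum;
          if (d0 != 0.0) {
            beta0 += d0;
            for (int j = 0; j < n; ++j) r[j] -= d0;
            double m = (wsum / n) * d0 * d0;
            if (m > dmax) dmax = m;
          }
        }
        ++sweeps;
        if (dmax > douter) douter = dmax;
        if (dmax < tol) { inner_done = true; break; }

        // iterate on the active (nonzero) set until stable
        while (sweeps < max_sweeps) {
          double dact = 0.0;
          for (int i = 0; i < p; ++i) {
            if (beta[i] == 0.0) continue;
            const double* xi = X.begin() + (std::size_t)i * n;
            double s = 0.0;
            for (int j = 0; j < n; ++j) s += w[j] * xi[j] * r[j];
            double num = s / n + v[i] * beta[i];
            double bn = soft(num, lam1) / (v[i] + lam2);
            double d = bn - beta[i];
            if (d != 0.0) {
              for (int j = 0; j < n; ++j) r[j] -= d * xi[j];
              beta[i] = bn;
              double m = v[i] * d * d;
              if (m > dact) dact = m;
            }
          }
          {
            double s = 0.0;
            for (int j = 0; j < n; ++j) s += w[j] * r[j];
            double d0 = s / wsum;
            if (d0 != 0.0) {
              beta0 += d0;
              for (int j = 0; j < n; ++j) r[j] -= d0;
              double m = (wsum / n) * d0 * d0;
              if (m > dact) dact = m;
            }
          }
          ++sweeps;
          if (dact > douter) douter = dact;
          if (dact < tol) break;
        }
        // loop back for a verifying full sweep
      }

      for (int j = 0; j < n; ++j) eta[j] = z[j] - r[j];
      if (trace) objs.push_back(penalized_obj(y, eta, beta, lam, alpha));
      if (douter < tol) { outer_conv = true; break; }
      if (sweeps >= max_sweeps) break;
    }

    conv[l] = outer_conv ? 1 : 0;
    sweeps_used[l] = sweeps;
    beta0_path[l] = beta0;
    for (int i = 0; i < p; ++i) beta_path(i, l) = beta[i];
    if (trace) obj_trace[l] = wrap(objs);
  }

  return List::create(_["beta0"] = beta0_path, _["beta"] = beta_path,
                      _["converged"] = conv, _["sweeps"] = sweeps_used,
                      _["obj_trace"] = obj_trace);
}
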