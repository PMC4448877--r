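#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// One EM run for a K-component mixture of simple linear regressions,
// starting from the responsibility matrix W0. Status: 0 = converged or
// iteration cap reached, 1 = degenerate (vanishing weight or variance
// pinned at the floor for 10 consecutive iterations), 2 = log-likelihood
// decreased (numerical failure; the caller raises an error).
// [[Rcpp::export]]
List em_run_cpp(NumericVector x, NumericVector y, int K, double tol,
                int max_iter, double sig_floor, NumericMatrix W0) {
  const int n = x.size();
  NumericMatrix W = clone(W0);
  NumericMatrix L(n, K);
  NumericVector p(K), b1(K), b2(K), s(K);
  IntegerVector floor_run(K);
  std::vector<double> trace;
  double ll_old = R_NegInf;
  int status = 0;
  const double LOG2PI = std::log(2.0 * M_PI);
  const double sf2 = sig_floor * sig_floor;

  for (int it = 0; it < max_iter && status == 0; ++it) {
    // M-step: weighted simple regression per component
    for (int j = 0; j < K; ++j) {
      double sw = 0, swx = 0, swy = 0;
      for (int i = 0; i < n; ++i) {
        const double w = W(i, j);
        sw += w; swx += w * x[i]; swy += w * y[i];
      }
      if (sw < 1.0) { status = 1; break; }
      const double mx = swx / sw, my = swy / sw;
      double sxx = 0, sxy = 0;
      for (int i = 0; i < n; ++i) {
        const double w = W(i, j), dx = x[i] - mx;
        sxx += w * dx * dx;
        sxy += w * dx * (y[i] - my);
      }
      const double beta2 = (sxx > 0) ? sxy / sxx : 0.0;
      const double beta1 = my - beta2 * mx;
      double rss = 0;
      for (int i = 0; i < n; ++i) {
        const double r = y[i] - beta1 - beta2 * x[i];
        rss += W(i, j) * r * r;
      }
      const double s2 = rss / sw;
      const double sj2 = (s2 > sf2) ? s2 : sf2;
      if (sj2 <= sf2 * (1 + 1e-12)) floor_run[j]++; else floor_run[j] = 0;
      p[j] = sw / n;
      b1[j] = beta1;
      b2[j] = beta2;
      s[j] = std::sqrt(sj2);
    }
    if (status != 0) break;
    for (int j = 0; j < K; ++j) {
      if (p[j] < 1.0 / n || floor_run[j] >= 10) { status = 1; }
    }
    if (status != 0) break;

    // E-step: responsibilities and observed-data log-likelihood
    double ll = 0;
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      for (int j = 0; j < K; ++j) {
        const double r = y[i] - b1[j] - b2[j] * x[i];
        const double lj = std::log(p[j]) - std::log(s[j]) - 0.5 * LOG2PI -
          0.5 * r * r / (s[j] * s[j]);
        L(i, j) = lj;
        if (lj > m) m = lj;
      }
      double sum = 0;
      for (int j = 0; j < K; ++j) sum += std::exp(L(i, j) - m);
      const double lse = m + std::log(sum);
      ll += lse;
      for (int j = 0; j < K; ++j) W(i, j) = std::exp(L(i, j) - lse);
    }
    if (R_FINITE(ll_old) && ll < ll_old - 1e-6 * (std::fabs(ll_old) + 1)) {
      status = 2;
      break;
    }
    trace.push_back(ll);
    bool at_floor = false;
    for (int j = 0; j < K; ++j) if (floor_run[j] > 0) at_floor = true;
    // convergence is only declared while no variance sits at its floor;
    // a pinned variance must either lift off or trip the degeneracy rule
    const bool conv = !at_floor && R_FINITE(ll_old) &&
      std::fabs(ll - ll_old) <= tol * (std::fabs(ll_old) + DBL_EPSILON);
    ll_old = ll;
    if (conv) break;
  }

  return List::create(
    _["p"] = p, _["beta1"] = b1, _["beta2"] = b2, _["sigma"] = s,
    _["loglik"] = trace.empty() ? NA_REAL : trace.back(),
    _["trace"] = wrap(trace),
    _["n_iter"] = (int)trace.size(),
    _["status"] = status);
}
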