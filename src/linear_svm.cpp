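#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// L2-regularised L1-loss linear SVC, solved in the dual by coordinate
// descent with shrinking (Hsieh et al. 2008). The bias is handled by
// augmenting every sample with a constant-1 feature; the stopping rule is
// the usual projected-gradient spread < eps (default 0.1).
//
// Deterministic: coordinate order is a permutation driven by an internal
// xorshift generator with a fixed seed, so a fit is a pure function of its
// inputs.

static inline uint32_t xorshift32(uint32_t &s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

static void dcd_solve(const std::vector<double> &xr, int n, int d,
                      const std::vector<double> &qii,
                      const std::vector<signed char> &y,
                      double cost, double eps, int max_iter,
                      std::vector<double> &w) {
  const double INF = 1e300;
  std::vector<double> alpha(n, 0.0);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::fill(w.begin(), w.end(), 0.0);
  uint32_t rng = 88172645u;
  int active = n;
  double pg_max_old = INF, pg_min_old = -INF;

  for (int iter = 0; iter < max_iter; ++iter) {
    double pg_max = -INF, pg_min = INF;
    for (int i = active - 1; i > 0; --i) {
      int j = xorshift32(rng) % (i + 1);
      std::swap(idx[i], idx[j]);
    }
    for (int s = 0; s < active; ++s) {
      int i = idx[s];
      double yi = (double)y[i];
      const double *xi = &xr[(size_t)i * d];
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      double g = yi * wx - 1.0;
      double pg = 0.0;
      if (alpha[i] == 0.0) {
        if (g > pg_max_old) {             // shrink
          --active;
          std::swap(idx[s], idx[active]);
          --s;
          continue;
        }
        if (g < 0.0) pg = g;
      } else if (alpha[i] == cost) {
        if (g < pg_min_old) {
          --active;
          std::swap(idx[s], idx[active]);
          --s;
          continue;
        }
        if (g > 0.0) pg = g;
      } else {
        pg = g;
      }
      if (pg > pg_max) pg_max = pg;
      if (pg < pg_min) pg_min = pg;
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > cost) a_new = cost;
        alpha[i] = a_new;
        double delta = (a_new - a_old) * yi;
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
          w[d] += delta;
        }
      }
    }
    if (pg_max - pg_min <= eps) {
      if (active == n) break;
      active = n;                         // unshrink and verify
      pg_max_old = INF;
      pg_min_old = -INF;
      continue;
    }
    pg_max_old = (pg_max <= 0.0) ? INF : pg_max;
    pg_min_old = (pg_min >= 0.0) ? -INF : pg_min;
  }
}

static void rowmajor_copy(const NumericMatrix &X, std::vector<double> &xr,
                          std::vector<double> &qii) {
  const int n = X.nrow(), d = X.ncol();
  xr.resize((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      xr[(size_t)i * d + j] = X(i, j);
  qii.resize(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0;                       // augmented bias feature
    const double *xi = &xr[(size_t)i * d];
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }
}

// Binary fit: y in {-1, +1}; returns the weight vector (last entry = bias).
// [[Rcpp::export]]
NumericVector svc_dcd_fit(const NumericMatrix &X, const IntegerVector &y,
                          double cost, double eps = 0.1,
                          int max_iter = 100) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> xr, qii, w(d + 1);
  rowmajor_copy(X, xr, qii);
  std::vector<signed char> yc(n);
  for (int i = 0; i < n; ++i) yc[i] = (signed char)((y[i] > 0) ? 1 : -1);
  dcd_solve(xr, n, d, qii, yc, cost, eps, max_iter, w);
  NumericVector out(d + 1);
  for (int j = 0; j <= d; ++j) out[j] = w[j];
  return out;
}

// One-vs-all fit: y holds 1-based class ids; returns (d + 1) x n_classes
// weights, one binary machine per column.
// [[Rcpp::export]]
NumericMatrix svc_ovr_fit(const NumericMatrix &X, const IntegerVector &y,
                          int n_classes, double cost, double eps = 0.1,
                          int max_iter = 100) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> xr, qii, w(d + 1);
  rowmajor_copy(X, xr, qii);
  NumericMatrix W(d + 1, n_classes);
  std::vector<signed char> yc(n);
  for (int c = 1; c <= n_classes; ++c) {
    for (int i = 0; i < n; ++i) yc[i] = (signed char)((y[i] == c) ? 1 : -1);
    dcd_solve(xr, n, d, qii, yc, cost, eps, max_iter, w);
    for (int j = 0; j <= d; ++j) W(j, c - 1) = w[j];
  }
  return W;
}
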