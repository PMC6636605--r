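#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// All-pairs shortest paths by Floyd-Warshall on a dense edge-length matrix.
// len(i,j) <= 0 or non-finite means "no edge"; the diagonal is ignored.
// Returns the full distance matrix (Inf where unreachable, 0 on diagonal).
// [[Rcpp::export]]
NumericMatrix apsp_lengths(NumericMatrix len) {
  const int n = len.nrow();
  if (len.ncol() != n) stop("edge-length matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = len(i, j);
      if (i == j)
        d[static_cast<size_t>(i) * n + j] = 0.0;
      else if (R_finite(v) && v > 0.0)
        d[static_cast<size_t>(i) * n + j] = v;
      else
        d[static_cast<size_t>(i) * n + j] = INF;
    }
  for (int k = 0; k < n; ++k) {
    const double* dk = &d[static_cast<size_t>(k) * n];
    for (int i = 0; i < n; ++i) {
      const double dik = d[static_cast<size_t>(i) * n + k];
      if (dik == INF) continue;
      double* di = &d[static_cast<size_t>(i) * n];
      for (int j = 0; j < n; ++j) {
        const double t = dik + dk[j];
        if (t < di[j]) di[j] = t;
      }
    }
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = d[static_cast<size_t>(i) * n + j];
  return out;
}

// Nodal global efficiency from a dense edge-length matrix:
// E_i = (1/(N-1)) * sum_{j != i} 1/d(i,j), unreachable pairs contribute 0.
// [[Rcpp::export]]
NumericVector nodal_efficiency_kernel(NumericMatrix len) {
  const int n = len.nrow();
  if (n < 2) stop("graph must have at least 2 nodes");
  NumericMatrix d = apsp_lengths(len);
  NumericVector eff(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dij = d(i, j);
      if (R_finite(dij) && dij > 0.0) s += 1.0 / dij;
    }
    eff[i] = s / (n - 1);
  }
  return eff;
}

// Coordinate descent for the penalized objective
//   ||y - X b||_2^2 + (lambda / 2) * ||b||_1
// on pre-standardized X and centered y. Soft-threshold at lambda/4 because
// d/db_j of the quadratic part is -2 x_j'r. Cycles full sweeps and
// active-set sweeps until the largest coordinate update is below tol.
// [[Rcpp::export]]
NumericVector lasso_cd(NumericMatrix X, NumericVector y, double lambda,
                       double tol = 1e-9, int max_sweeps = 100000) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("dimension mismatch");
  std::vector<double> beta(p, 0.0), r(y.begin(), y.end()), xx(p, 0.0);
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xx[j] = s;
  }
  const double thr = lambda / 4.0;
  std::vector<char> active(p, 0);
  bool active_only = false;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double maxdelta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (active_only && !active[j]) continue;
      if (xx[j] <= 0.0) continue;
      const double* xj = &X(0, j);
      double c = 0.0;
      for (int i = 0; i < n; ++i) c += xj[i] * r[i];
      c += beta[j] * xx[j];
      double bnew = 0.0;
      if (c > thr) bnew = (c - thr) / xx[j];
      else if (c < -thr) bnew = (c + thr) / xx[j];
      const double d = bnew - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
        beta[j] = bnew;
        const double ad = d < 0 ? -d : d;
        if (ad > maxdelta) maxdelta = ad;
      }
      active[j] = beta[j] != 0.0;
    }
    if (maxdelta < tol) {
      if (!active_only) break;      // converged on a full sweep
      active_only = false;          // verify with a full sweep
    } else {
      active_only = true;
    }
  }
  return NumericVector(beta.begin(), beta.end());
}
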