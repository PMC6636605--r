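// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Homotopy (LARS-lasso) path solution of
//   min ||y - X b||^2 + (lambda / 2) * ||b||_1
// on standardized X / centered y. Active features satisfy
// x_j' r = mu * sign(b_j) with mu = lambda / 4; the path
//   b_A(mu) = (X_A'X_A)^{-1} (X_A'y - mu * s_A)
// is piecewise linear in mu, so mu is lowered from max|x'y| through
// join/drop events until the target. Returns an empty vector on numerical
// failure (near-singular active Gram, step-count overrun) so the R caller
// can fall back to coordinate descent.
// [[Rcpp::export]]
arma::vec lasso_homotopy_cpp(const arma::mat& X, const arma::vec& y,
                             double lambda, int max_steps = 0) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const double mu_t = lambda / 4.0;
  if (max_steps <= 0) max_steps = 4 * static_cast<int>(std::min(n, p)) + 100;
  arma::vec cy = X.t() * y;
  arma::uword j0 = arma::abs(cy).index_max();
  double mu = std::abs(cy(j0));
  if (mu <= mu_t) return arma::zeros(p);
  const arma::uword maxA = std::min(n, p) + 1;
  arma::mat G(p, maxA);                 // Gram block X' X_A, grown in place
  G.col(0) = X.t() * X.col(j0);
  std::vector<arma::uword> A{j0};
  std::vector<double> sA{cy(j0) > 0 ? 1.0 : -1.0};
  std::vector<char> active(p, 0);
  active[j0] = 1;
  const double eps = 1e-12;
  arma::vec empty;
  for (int step = 0; step < max_steps; ++step) {
    const arma::uword k = A.size();
    if (k >= maxA) return empty;
    arma::uvec Ai(A);
    arma::vec sv(sA);
    arma::mat Gk = G.cols(0, k - 1);
    arma::mat GA = Gk.rows(Ai);
    arma::mat R;
    if (!arma::chol(R, GA)) return empty;
    if (R.diag().min() < 1e-7) return empty;
    arma::vec aA = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), cy(Ai)));
    arma::vec bA = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), sv));
    arma::vec u = cy - Gk * aA;        // c_j(mu) = u_j + mu * v_j
    arma::vec v = Gk * bA;
    double cand_mu = mu_t;
    arma::sword event = -1;
    double event_sign = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      if (active[j]) continue;
      for (int s = -1; s <= 1; s += 2) {
        const double denom = s - v(j);
        if (std::abs(denom) <= eps) continue;
        const double m = u(j) / denom;
        if (m < mu - 1e-9 && m > cand_mu + 1e-12) {
          cand_mu = m;
          event = static_cast<arma::sword>(j);
          event_sign = s;
        }
      }
    }
    arma::sword drop_pos = -1;
    for (arma::uword t = 0; t < k; ++t) {
      if (std::abs(bA(t)) <= eps) continue;
      const double m = aA(t) / bA(t);
      if (m < mu - 1e-9 && m > cand_mu + 1e-12) {
        cand_mu = m;
        drop_pos = static_cast<arma::sword>(t);
        event = -1;
      }
    }
    if (event < 0 && drop_pos < 0) {   // no event above target: finish
      arma::vec beta = arma::zeros(p);
      beta(Ai) = aA - mu_t * bA;
      return beta;
    }
    mu = cand_mu;
    if (drop_pos >= 0) {
      const arma::uword t = static_cast<arma::uword>(drop_pos);
      active[A[t]] = 0;
      for (arma::uword q = t; q + 1 < k; ++q) G.col(q) = G.col(q + 1);
      A.erase(A.begin() + t);
      sA.erase(sA.begin() + t);
      if (A.empty()) return empty;
    } else {
      const arma::uword j = static_cast<arma::uword>(event);
      G.col(k) = X.t() * X.col(j);
      A.push_back(j);
      sA.push_back(event_sign);
      active[j] = 1;
    }
  }
  return empty;
}
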