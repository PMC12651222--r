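// Cyclic coordinate descent for the elastic-net penalized least squares
//
//   L(beta) = 1/(2n) ||y - X beta||^2 + lambda * ( alpha ||beta||_1
//                                                + (1-alpha)/2 ||beta||_2^2 )
//
// solved over a descending lambda path with warm starts. Sweeps alternate
// between the active set (non-zero coefficients) and all features; a full
// sweep that moves nothing below tolerance certifies convergence. The
// objective is recorded after every sweep so monotone descent can be
// asserted. Intercept handling (column standardization, response
// centering) is done by the R callers.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static double enet_objective(const vec& r, const vec& beta, double lambda,
                             double alpha, double n) {
  return 0.5 / n * dot(r, r) +
         lambda * (alpha * accu(abs(beta)) + 0.5 * (1 - alpha) * dot(beta, beta));
}

// [[Rcpp::export]]
Rcpp::List enet_path_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::vec& lambdas, double alpha, double tol,
                         int max_sweeps) {
  const uword n = X.n_rows, p = X.n_cols;
  const uword L = lambdas.n_elem;
  vec v(p);  // (1/n) sum x_ij^2 per column
  for (uword j = 0; j < p; ++j) v(j) = dot(X.col(j), X.col(j)) / double(n);

  mat betas(p, L, fill::zeros);
  vec beta(p, fill::zeros);
  vec r = y;  // residual y - X beta
  Rcpp::List obj_hist(L);
  std::vector<int> sweeps(L);
  std::vector<uword> active;
  active.reserve(p);
  double cur_l1 = 0.0, cur_l2 = 0.0;

  auto sweep_over = [&](const std::vector<uword>* subset) -> double {
    double max_change = 0.0;
    const uword m = subset ? subset->size() : p;
    for (uword t = 0; t < m; ++t) {
      const uword j = subset ? (*subset)[t] : t;
      if (v(j) <= 0) { beta(j) = 0; continue; }
      const double bj = beta(j);
      const double rho = dot(X.col(j), r) / double(n) + v(j) * bj;
      const double bnew = soft_threshold(rho, cur_l1) / (v(j) + cur_l2);
      if (bnew != bj) {
        r -= (bnew - bj) * X.col(j);
        beta(j) = bnew;
        const double ch = std::abs(bnew - bj);
        if (ch > max_change) max_change = ch;
      }
    }
    return max_change;
  };

  for (uword l = 0; l < L; ++l) {
    const double lam = lambdas(l);
    cur_l1 = lam * alpha;
    cur_l2 = lam * (1 - alpha);
    std::vector<double> objs;
    int s = 0;
    bool converged = false;
    while (s < max_sweeps && !converged) {
      // full sweep (also refreshes the active set)
      double ch = sweep_over(nullptr);
      ++s;
      objs.push_back(enet_objective(r, beta, lam, alpha, double(n)));
      if (ch < tol) { converged = true; break; }
      active.clear();
      for (uword j = 0; j < p; ++j) if (beta(j) != 0) active.push_back(j);
      // iterate the active set to convergence before the next full sweep
      while (s < max_sweeps) {
        double cha = sweep_over(&active);
        ++s;
        objs.push_back(enet_objective(r, beta, lam, alpha, double(n)));
        if (cha < tol) break;
      }
    }
    sweeps[l] = s;
    obj_hist[l] = objs;
    betas.col(l) = beta;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = betas,
                            Rcpp::Named("objective") = obj_hist,
                            Rcpp::Named("sweeps") = sweeps);
}
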