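// Quantile regression: IRLS warm start + exact simplex (exterior-point)
// descent on the piecewise-linear check loss. An optimal solution is a
// basic solution interpolating p observations; starting from the basis
// suggested by IRLS, each step drops one basis point, moves along the
// one-dimensional null direction via a weighted-median line search, and
// admits the blocking observation into the basis. Terminates when no
// one-sided directional derivative is negative, i.e. at a global optimum
// of the convex objective. The bootstrap driver refits all requested
// quantiles on caller-supplied resample indices so the RNG stays in R.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>

static double check_loss(const arma::vec& r, double q) {
  double s = 0.0;
  for (arma::uword i = 0; i < r.n_elem; ++i) {
    double u = r[i];
    s += u * (q - (u < 0.0 ? 1.0 : 0.0));
  }
  return s;
}

// Pick an initial nonsingular basis from the smallest-|residual| rows.
static bool initial_basis(const arma::mat& X, const arma::vec& r,
                          arma::uvec& h) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::uvec ord = arma::sort_index(arma::abs(r));
  h.set_size(p);
  arma::uword have = 0;
  arma::mat B(p, p);
  for (arma::uword t = 0; t < n && have < p; ++t) {
    B.row(have) = X.row(ord[t]);
    if (arma::rank(B.rows(0, have)) == have + 1) h[have++] = ord[t];
  }
  return have == p;
}

// One-sided directional derivative of sum rho_q along direction d at the
// current residuals r (zero residuals contribute their one-sided kink).
static double dir_deriv(const arma::vec& r, const arma::vec& u, double q,
                        double ztol) {
  double D = 0.0;
  for (arma::uword i = 0; i < r.n_elem; ++i) {
    double v = -u[i];  // d r_i / d t
    if (std::abs(r[i]) > ztol)
      D += v * (q - (r[i] < 0.0 ? 1.0 : 0.0));
    else
      D += v * (q - (v < 0.0 ? 1.0 : 0.0));  // kink: worst (largest) side
  }
  return D;
}

// Exact descent from a basic solution; returns the optimal coefficients.
static void simplex_descent(const arma::mat& X, const arma::vec& y,
                            double q, arma::vec& best, double& best_obj,
                            int max_steps) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec r = y - X * best;
  arma::uvec h;
  if (!initial_basis(X, r, h)) return;
  arma::vec b;
  if (!arma::solve(b, X.rows(h), y.elem(h),
                   arma::solve_opts::no_approx))
    return;
  double obj = check_loss(y - X * b, q);
  if (obj < best_obj) { best_obj = obj; best = b; }
  const double ztol = 1e-9;

  for (int step = 0; step < max_steps; ++step) {
    r = y - X * b;
    bool moved = false;
    for (arma::uword k = 0; k < p && !moved; ++k) {
      // null direction of the basis without point k
      arma::mat Xh = X.rows(h);
      arma::mat A(p - 1, p);
      arma::uword row = 0;
      for (arma::uword j = 0; j < p; ++j)
        if (j != k) A.row(row++) = Xh.row(j);
      arma::mat N = arma::null(A);
      if (N.n_cols != 1) continue;  // degenerate basis
      arma::vec d = N.col(0);
      for (int sgn = 0; sgn < 2 && !moved; ++sgn) {
        arma::vec dd = sgn == 0 ? d : arma::vec(-d);
        arma::vec u = X * dd;          // residual change rate is -u
        double D = dir_deriv(r, u, q, ztol);
        if (D >= -1e-10) continue;
        // weighted-median line search: passing t_i = r_i/u_i flips point
        // i's gradient contribution by |u_i|
        std::vector<std::pair<double, double>> cuts;  // (t, |u_i|)
        for (arma::uword i = 0; i < n; ++i) {
          if (std::abs(u[i]) < 1e-12) continue;
          double t = r[i] / u[i];
          if (t > 1e-12) cuts.emplace_back(t, std::abs(u[i]));
        }
        if (cuts.empty()) continue;  // unbounded descent (degenerate)
        std::sort(cuts.begin(), cuts.end());
        double t_star = -1.0;
        for (auto& c : cuts) {
          D += c.second;
          if (D >= -1e-12) { t_star = c.first; break; }
        }
        if (t_star < 0) t_star = cuts.back().first;
        arma::vec b_new = b + t_star * dd;
        double obj_new = check_loss(y - X * b_new, q);
        if (obj_new < best_obj - 1e-12) {
          // entering observation: the zero-residual point at t_star
          arma::vec r_new = y - X * b_new;
          arma::uword enter = n;
          double bestz = 1e99;
          for (arma::uword i = 0; i < n; ++i) {
            bool inb = false;
            for (arma::uword j = 0; j < p; ++j) if (h[j] == i) inb = true;
            if (!inb && std::abs(r_new[i]) < bestz) {
              bestz = std::abs(r_new[i]);
              enter = i;
            }
          }
          if (enter == n) continue;
          h[k] = enter;
          arma::vec b_ref;
          if (arma::solve(b_ref, X.rows(h), y.elem(h),
                          arma::solve_opts::no_approx)) {
            double obj_ref = check_loss(y - X * b_ref, q);
            if (obj_ref <= obj_new) { b_new = b_ref; obj_new = obj_ref; }
          }
          b = b_new;
          best = b_new;
          best_obj = obj_new;
          moved = true;
        }
      }
    }
    if (!moved) break;
  }
}

static arma::vec qr_fit_one(const arma::mat& X, const arma::vec& y, double q,
                            int max_it, double tol, bool polish) {
  arma::vec b;
  if (!arma::solve(b, X, y))
    return arma::vec(X.n_cols).fill(arma::datum::nan);
  arma::vec best = b;
  double best_obj = check_loss(y - X * b, q);
  const double eps = 1e-9;
  for (int it = 0; it < max_it; ++it) {
    arma::vec r = y - X * b;
    arma::vec sw(r.n_elem);
    for (arma::uword i = 0; i < r.n_elem; ++i) {
      double c = r[i] > 0.0 ? q : 1.0 - q;
      sw[i] = std::sqrt(c / std::max(std::abs(r[i]), eps));
    }
    arma::mat Xw = X.each_col() % sw;
    arma::vec yw = y % sw;
    arma::vec bn;
    if (!arma::solve(bn, Xw, yw)) break;
    double obj = check_loss(y - X * bn, q);
    if (obj < best_obj) { best_obj = obj; best = bn; }
    if (arma::norm(bn - b, "inf") < tol * (1.0 + arma::norm(b, "inf"))) {
      b = bn;
      break;
    }
    b = bn;
  }
  if (polish) simplex_descent(X, y, q, best, best_obj, 200);
  return best;
}

// [[Rcpp::export(name = ".qr_fit_cpp")]]
Rcpp::NumericVector qr_fit_cpp(const arma::mat& X, const arma::vec& y,
                               double q, int max_it = 100,
                               double tol = 1e-10, bool polish = true) {
  arma::vec b = qr_fit_one(X, y, q, max_it, tol, polish);
  return Rcpp::NumericVector(b.begin(), b.end());
}

// [[Rcpp::export(name = ".qr_objective_cpp")]]
double qr_objective_cpp(const arma::mat& X, const arma::vec& y,
                        const arma::vec& b, double q) {
  return check_loss(y - X * b, q);
}

// Bootstrap driver: idx is an n x B matrix of 1-based resample indices.
// Returns a B x (p * n_q) matrix; columns are grouped by quantile.
// [[Rcpp::export(name = ".qr_boot_cpp")]]
arma::mat qr_boot_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::vec& qs, const arma::umat& idx,
                      int max_it = 50, double tol = 1e-8,
                      bool polish = true) {
  const arma::uword B = idx.n_cols, p = X.n_cols, nq = qs.n_elem;
  arma::mat out(B, p * nq);
  out.fill(arma::datum::nan);
  for (arma::uword b = 0; b < B; ++b) {
    arma::uvec rows = idx.col(b) - 1;
    arma::mat Xb = X.rows(rows);
    arma::vec yb = y.elem(rows);
    if (arma::rank(Xb) < p) continue;  // degenerate resample
    for (arma::uword k = 0; k < nq; ++k) {
      arma::vec bk = qr_fit_one(Xb, yb, qs[k], max_it, tol, polish);
      if (bk.is_finite()) out(b, arma::span(k * p, (k + 1) * p - 1)) = bk.t();
    }
  }
  return out;
}
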