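// Dense two-phase revised simplex used for the zonotope containment program
//   min beta_max  s.t.  G beta = y,  |beta_j| <= beta_max.
// Written here because no general LP solver is available to the package at
// run time; the formulation below is the standard split-variable standard form
//   x = (beta+, beta-, s, t) >= 0
//   rows 1..p:   beta+_j + beta-_j + s_j - t = 0
//   rows p+1..p+4:  G (beta+ - beta-) = y
// with artificial columns on the last four rows for phase 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

constexpr double kTol = 1e-9;

struct SimplexResult {
  vec x;
  double obj;
  int status; // 0 ok, 1 infeasible, 2 iteration limit, 3 unbounded
};

// Revised simplex, minimisation, requires an initial basis whose columns form
// an identity (after row scaling by the caller) so Binv starts as I.
SimplexResult simplex_min(const mat& A, const sp_mat& As, const vec& b,
                          const vec& c, uvec basis, const uvec& blocked,
                          int max_iter) {
  const uword m = A.n_rows, n = A.n_cols;
  mat Binv = eye(m, m);
  vec xB = b; // valid because initial basis columns are unit vectors
  int degenerate_run = 0;
  bool bland = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    if (iter > 0 && iter % 256 == 0) { // refactorise for numerical hygiene
      mat B(m, m);
      for (uword i = 0; i < m; ++i) B.col(i) = A.col(basis(i));
      mat Bi;
      if (!inv(Bi, B)) break;
      Binv = Bi;
      xB = Binv * b;
    }
    vec yrow = Binv.t() * c(conv_to<uvec>::from(basis));
    // reduced costs (sparse pricing: A has ~12 p nonzeros)
    rowvec d = c.t() - rowvec(yrow.t() * As);
    // basic columns and blocked columns are ineligible
    for (uword i = 0; i < m; ++i) d(basis(i)) = 0.0;
    for (uword k = 0; k < blocked.n_elem; ++k) d(blocked(k)) = 0.0;

    sword enter = -1;
    if (!bland) {
      double best = -kTol * 10;
      for (uword j = 0; j < n; ++j)
        if (d(j) < best) { best = d(j); enter = j; }
    } else {
      for (uword j = 0; j < n; ++j)
        if (d(j) < -kTol * 10) { enter = j; break; }
    }
    if (enter < 0) {
      SimplexResult res{vec(n, fill::zeros), 0.0, 0};
      for (uword i = 0; i < m; ++i) res.x(basis(i)) = xB(i);
      res.obj = dot(c, res.x);
      return res;
    }

    vec w = Binv * A.col(enter);
    sword leave = -1;
    double best_ratio = datum::inf;
    for (uword i = 0; i < m; ++i) {
      if (w(i) > kTol) {
        double ratio = xB(i) / w(i);
        if (ratio < best_ratio - kTol ||
            (bland && std::abs(ratio - best_ratio) <= kTol && leave >= 0 &&
             basis(i) < basis(leave))) {
          best_ratio = ratio;
          leave = i;
        }
      }
    }
    if (leave < 0) {
      return SimplexResult{vec(n, fill::zeros), datum::inf, 3};
    }
    if (best_ratio <= kTol) {
      if (++degenerate_run > 64) bland = true;
    } else {
      degenerate_run = 0;
      bland = false;
    }

    // pivot: update Binv and xB
    double piv = w(leave);
    vec binv_leave = Binv.row(leave).t() / piv;
    for (uword i = 0; i < m; ++i) {
      if ((sword)i == leave) continue;
      Binv.row(i) -= w(i) * binv_leave.t();
      xB(i) -= w(i) * best_ratio;
    }
    Binv.row(leave) = binv_leave.t();
    xB(leave) = best_ratio;
    basis(leave) = enter;
  }
  return SimplexResult{vec(A.n_cols, fill::zeros), datum::nan, 2};
}

} // namespace

// [[Rcpp::export(name = ".zn_beta_lp")]]
Rcpp::List zn_beta_lp(const arma::mat& G, const arma::vec& y, int max_iter = 50000) {
  const uword nd = G.n_rows, p = G.n_cols;
  // columns: beta+ (p), beta- (p), s (p), t (1), artificials (nd)
  const uword n = 3 * p + 1 + nd;
  const uword m = p + nd;
  mat A(m, n, fill::zeros);
  vec b(m, fill::zeros), c(n, fill::zeros);

  for (uword j = 0; j < p; ++j) {
    A(j, j) = 1.0;          // beta+_j
    A(j, p + j) = 1.0;      // beta-_j
    A(j, 2 * p + j) = 1.0;  // s_j
    A(j, 3 * p) = -1.0;     // -t
  }
  for (uword i = 0; i < nd; ++i) {
    double sgn = (y(i) >= 0) ? 1.0 : -1.0; // make rhs nonnegative
    for (uword j = 0; j < p; ++j) {
      A(p + i, j) = sgn * G(i, j);
      A(p + i, p + j) = -sgn * G(i, j);
    }
    A(p + i, 3 * p + 1 + i) = 1.0; // artificial
    b(p + i) = sgn * y(i);
  }

  uvec basis(m);
  for (uword j = 0; j < p; ++j) basis(j) = 2 * p + j;       // s_j
  for (uword i = 0; i < nd; ++i) basis(p + i) = 3 * p + 1 + i; // artificials

  // single big-M solve from the identity basis; artificials heavily
  // penalised relative to an a-priori feasible bound on t (least-squares
  // representation), so optimality drives them to zero whenever y lies in
  // the column space of G.
  double t_ub = 1.0;
  {
    // least-squares representation via regularised normal equations: any
    // feasible beta bounds the optimum, and this avoids warnings on
    // rank-deficient G
    mat GGt = G * G.t();
    double reg = 1e-12 * (1.0 + trace(GGt));
    vec beta_ls = G.t() * solve(GGt + reg * eye(nd, nd), y,
                                solve_opts::likely_sympd);
    t_ub = std::max(1.0, norm(beta_ls, "inf"));
  }
  c(3 * p) = 1.0; // minimise t
  double bigM = 1e6 * t_ub;
  for (uword i = 0; i < nd; ++i) c(3 * p + 1 + i) = bigM;
  SimplexResult ph2 = simplex_min(A, sp_mat(A), b, c, basis, uvec(), max_iter);
  if (ph2.status != 0) {
    return Rcpp::List::create(Rcpp::Named("beta_max") = R_NaReal,
                              Rcpp::Named("beta") = Rcpp::NumericVector(p),
                              Rcpp::Named("status") = ph2.status);
  }
  double art = 0;
  for (uword i = 0; i < nd; ++i) art += ph2.x(3 * p + 1 + i);
  if (art > 1e-6 * (1.0 + norm(y, 2))) {
    return Rcpp::List::create(Rcpp::Named("beta_max") = R_PosInf,
                              Rcpp::Named("beta") = Rcpp::NumericVector(p),
                              Rcpp::Named("status") = 1);
  }
  vec beta = ph2.x.subvec(0, p - 1) - ph2.x.subvec(p, 2 * p - 1);
  return Rcpp::List::create(Rcpp::Named("beta_max") = ph2.x(3 * p),
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("status") = 0);
}
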