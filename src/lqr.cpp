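// Finite-horizon discrete-time Riccati recursion and the fitting objective
// for the LQR controller model. These sit inside a grid + Nelder-Mead weight
// search, so they are the hot loop of controller fitting.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Backward Riccati recursion with terminal cost P_N = Q on the ZOH pair
// (Ad, Bd). Returns the 2x4 gain at each of the n_steps intervals.
// [[Rcpp::export(name = ".lqr_riccati")]]
arma::cube lqr_riccati(const arma::mat& Ad, const arma::mat& Bd,
                       const arma::mat& Q, const arma::mat& R, int n_steps) {
  const uword nu = Bd.n_cols, nx = Ad.n_rows;
  cube K(nu, nx, n_steps);
  mat P = Q;
  for (int k = n_steps - 1; k >= 0; --k) {
    mat BtP = Bd.t() * P;
    mat Kk = solve(R + BtP * Bd, BtP * Ad, solve_opts::likely_sympd);
    mat Acl = Ad - Bd * Kk;
    P = Q + Kk.t() * R * Kk + Acl.t() * P * Acl;
    P = 0.5 * (P + P.t());
    K.slice(k) = Kk;
  }
  return K;
}

// Summed squared input error of the LQR law u = u_ol - K (x - xbar) against
// observed inputs over the first n_steps grid points, masked per sample.
// X: nx x nT x ntrials, U: nu x nT x ntrials, mask: nT x ntrials.
// [[Rcpp::export(name = ".lqr_objective")]]
double lqr_objective(const arma::cube& K, const arma::mat& Xbar,
                     const arma::mat& Uol, const arma::cube& X,
                     const arma::cube& U, const arma::imat& mask) {
  const uword n_steps = K.n_slices, ntr = X.n_slices;
  double obj = 0.0;
  for (uword k = 0; k < n_steps; ++k) {
    const mat& Kk = K.slice(k);
    for (uword i = 0; i < ntr; ++i) {
      if (!mask(k, i)) continue;
      vec upred = Uol.col(k) - Kk * (X.slice(i).col(k) - Xbar.col(k));
      vec e = upred - U.slice(i).col(k);
      obj += dot(e, e);
    }
  }
  return obj;
}

// Convenience wrapper: build diagonal weights, run the recursion, evaluate
// the objective. qdiag = (Q22, Q33, Q44) with Q11 fixed at 1.
// [[Rcpp::export(name = ".lqr_fit_obj")]]
double lqr_fit_obj(const arma::mat& Ad, const arma::mat& Bd,
                   const arma::vec& qdiag, const arma::vec& rdiag,
                   const arma::mat& Xbar, const arma::mat& Uol,
                   const arma::cube& X, const arma::cube& U,
                   const arma::imat& mask) {
  mat Q = diagmat(vec({1.0, qdiag(0), qdiag(1), qdiag(2)}));
  mat R = diagmat(rdiag);
  cube K = lqr_riccati(Ad, Bd, Q, R, mask.n_rows > 0 ? Xbar.n_cols - 1 : 0);
  return lqr_objective(K, Xbar, Uol, X, U, mask);
}

// Per-axis objective: the point-mass dynamics, diagonal weights and summed
// squared input error all decouple into the horizontal and vertical 2x2
// subsystems, so the weight search can be run per axis. Hand-expanded
// scalar recursion for speed (this sits inside a grid search).
// Ad = [[1, dt], [0, 1]], Bd = (dt^2/2m, dt/m); Q = diag(q1, q2), R = r.
// [[Rcpp::export(name = ".lqr_axis_obj")]]
double lqr_axis_obj(double dt, double mass, double q1, double q2, double r,
                    const arma::mat& Xbar2, const arma::vec& Uol1,
                    const arma::cube& X2, const arma::mat& U1,
                    const arma::imat& mask) {
  const int n_steps = Xbar2.n_cols - 1;
  const int ntr = X2.n_slices;
  const double b1 = dt * dt / (2.0 * mass), b2 = dt / mass;
  std::vector<double> K1(n_steps), K2(n_steps);
  double p11 = q1, p12 = 0.0, p22 = q2;
  for (int k = n_steps - 1; k >= 0; --k) {
    double s1 = b1 * p11 + b2 * p12;
    double s2 = b1 * p12 + b2 * p22;
    double den = r + s1 * b1 + s2 * b2;
    double k1 = s1 / den;
    double k2 = (s1 * dt + s2) / den;
    K1[k] = k1; K2[k] = k2;
    double a11 = 1.0 - b1 * k1, a12 = dt - b1 * k2;
    double a21 = -b2 * k1, a22 = 1.0 - b2 * k2;
    // P' = Q + r K'K + Acl' P Acl
    double m11 = p11 * a11 + p12 * a21, m12 = p11 * a12 + p12 * a22;
    double m21 = p12 * a11 + p22 * a21, m22 = p12 * a12 + p22 * a22;
    double n11 = a11 * m11 + a21 * m21;
    double n12 = a11 * m12 + a21 * m22;
    double n22 = a12 * m12 + a22 * m22;
    p11 = q1 + r * k1 * k1 + n11;
    p12 = r * k1 * k2 + n12;
    p22 = q2 + r * k2 * k2 + n22;
  }
  double obj = 0.0;
  for (int k = 0; k < n_steps; ++k) {
    for (int i = 0; i < ntr; ++i) {
      if (!mask(k, i)) continue;
      double dx1 = X2(0, k, i) - Xbar2(0, k);
      double dx2 = X2(1, k, i) - Xbar2(1, k);
      double e = Uol1(k) - K1[k] * dx1 - K2[k] * dx2 - U1(k, i);
      obj += e * e;
    }
  }
  return obj;
}
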