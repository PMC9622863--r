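// Exact propagation of linear (affine / polynomially forced) ODE systems on a
// time grid via matrix exponentials of augmented systems, plus the DL-MRA sum
// of squared errors.  These are the hot paths of the multistart estimator: a
// single fit evaluates the objective thousands of times, so the per-candidate
// model (always linear, even when the data come from nonlinear generators) is
// propagated exactly rather than by adaptive integration.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Propagate z' = A z across the grid, returning the first n_keep state
// components at every time point.  The grid need not be even; consecutive
// equal steps reuse one matrix exponential.
static mat propagate(const mat& A, const vec& z0, const vec& times,
                     const unsigned int n_keep) {
  const unsigned int nt = times.n_elem;
  mat out(nt, n_keep);
  vec z = z0;
  out.row(0) = z.head(n_keep).t();
  mat E;
  double last_dt = datum::nan;
  bool ok = true;
  for (unsigned int k = 0; k + 1 < nt; ++k) {
    const double dt = times[k + 1] - times[k];
    if (ok && (k == 0 || dt != last_dt)) {
      ok = expmat(E, A * dt);
      last_dt = dt;
    }
    if (!ok) {
      out.rows(k + 1, nt - 1).fill(datum::inf);
      return out;
    }
    z = E * z;
    out.row(k + 1) = z.head(n_keep).t();
  }
  return out;
}

// x' = F x + s from x0, solved exactly on the grid.
// [[Rcpp::export]]
arma::mat prop_affine_cpp(const arma::mat& F, const arma::vec& s,
                          const arma::vec& x0, const arma::vec& times) {
  const unsigned int n = x0.n_elem;
  mat A(n + 1, n + 1, fill::zeros);
  A.submat(0, 0, n - 1, n - 1) = F;
  A.submat(0, n, n - 1, n) = s;
  vec z0(n + 1);
  z0.head(n) = x0;
  z0[n] = 1.0;
  return propagate(A, z0, times, n);
}

// x' = Fs x + b + g * P(t) with P a polynomial (coefficients `pc`, ascending
// powers of t).  The monomial basis (1, t, ..., t^m) is appended to the state
// so the system stays autonomous and admits an exact exponential propagator.
// [[Rcpp::export]]
arma::mat prop_forced_cpp(const arma::mat& Fs, const arma::vec& b,
                          const arma::vec& g, const arma::vec& pc,
                          const arma::vec& x0, const arma::vec& times) {
  const unsigned int n = x0.n_elem;
  const unsigned int m = pc.n_elem;
  mat A(n + m, n + m, fill::zeros);
  A.submat(0, 0, n - 1, n - 1) = Fs;
  mat C = g * pc.t();            // forcing enters through the monomial basis
  C.col(0) += b;
  A.submat(0, n, n - 1, n + m - 1) = C;
  for (unsigned int i = 1; i < m; ++i)  // d t^i / dt = i t^(i-1)
    A(n + i, n + i - 1) = static_cast<double>(i);
  vec z0(n + m);
  z0.head(n) = x0;
  for (unsigned int i = 0; i < m; ++i) z0[n + i] = std::pow(times[0], i);
  return propagate(A, z0, times, n);
}

// DL-MRA objective Phi: sum of squared residuals between measured and
// model-predicted trajectories over the vehicle condition and every
// perturbation condition, excluding node j's residuals under perturbation j
// (whose measured trace instead forces the surrogate ODE via `pc`).
//
// theta layout by variant:
//   0 standard:   n^2 edge weights (column-major F), then n external stimuli;
//                 basal production eliminated as S_b = -F x(0) (vehicle t=0).
//   1 zero_basal: as standard but S_b fixed at 0.
//   2 ffl:        n = 3; 9 edge weights then S_1,ex; S_2,ex = S_3,ex = 0,
//                 S_1,b = 0, S_2,b / S_3,b eliminated from rows 2-3 of -F x(0).
//   3 cellstate:  n(n-1) off-diagonal rates (column-major, skipping the
//                 diagonal); F_jj = -sum of column j off-diagonals;
//                 S_b = S_ex = 0.
//
// spec: list(n, variant, times, vehicle, perturbed, pc) where `perturbed` is
// a list of Nt x n matrices (condition j = perturbation of node j) and `pc`
// the list of ascending polynomial coefficients fitted to each perturbed
// node's own measured trace.
// Residual vector for the same problem, used by the damped (Levenberg-
// Marquardt) path; non-finite entries are replaced by a large finite value
// so damped least squares can recover from wild candidates.
// [[Rcpp::export]]
arma::vec dlmra_resid_cpp(const arma::vec& theta, const Rcpp::List& spec) {
  const unsigned int n = Rcpp::as<unsigned int>(spec["n"]);
  const int variant = Rcpp::as<int>(spec["variant"]);
  const vec times = Rcpp::as<vec>(spec["times"]);
  const mat veh = Rcpp::as<mat>(spec["vehicle"]);
  const Rcpp::List pert(spec["perturbed"]);
  const Rcpp::List pcs(spec["pc"]);
  const unsigned int nt = times.n_elem;

  mat F(n, n);
  vec S_ex(n, fill::zeros), S_b(n, fill::zeros);
  if (variant == 3) {
    unsigned int idx = 0;
    for (unsigned int j = 0; j < n; ++j) {
      double colsum = 0.0;
      for (unsigned int i = 0; i < n; ++i) {
        if (i == j) continue;
        F(i, j) = theta[idx++];
        colsum += F(i, j);
      }
      F(j, j) = -colsum;
    }
  } else {
    F = reshape(theta.head(n * n), n, n);
    const vec x0 = veh.row(0).t();
    if (variant == 0) {
      S_ex = theta.subvec(n * n, n * n + n - 1);
      S_b = -(F * x0);
    } else if (variant == 1) {
      S_ex = theta.subvec(n * n, n * n + n - 1);
    } else {  // ffl
      S_ex[0] = theta[n * n];
      const vec q = -(F * x0);
      for (unsigned int i = 1; i < n; ++i) S_b[i] = q[i];
    }
  }
  const vec s = S_b + S_ex;

  vec out(nt * n + nt * (n - 1) * n);
  unsigned int pos = 0;
  {
    const mat pred = prop_affine_cpp(F, s, veh.row(0).t(), times);
    const mat r = veh - pred;
    out.subvec(pos, pos + r.n_elem - 1) = vectorise(r);
    pos += r.n_elem;
  }
  for (unsigned int j = 0; j < n; ++j) {
    const mat xj = Rcpp::as<mat>(pert[j]);
    const vec pc = Rcpp::as<vec>(pcs[j]);
    const uvec keep = find(regspace<uvec>(0, n - 1) != j);
    const mat Fs = F.submat(keep, keep);
    const vec g = F.col(j);
    const vec x0p = vec(xj.row(0).t()).elem(keep);
    const mat pred = prop_forced_cpp(Fs, s.elem(keep), g.elem(keep), pc,
                                     x0p, times);
    const mat r = xj.cols(keep) - pred;
    out.subvec(pos, pos + r.n_elem - 1) = vectorise(r);
    pos += r.n_elem;
  }
  out.transform([](double v) {
    return std::isfinite(v) ? v : 1e6;
  });
  return out;
}

// [[Rcpp::export]]
double dlmra_phi_cpp(const arma::vec& theta, const Rcpp::List& spec) {
  const vec r = dlmra_resid_cpp(theta, spec);
  double phi = dot(r, r);
  if (!std::isfinite(phi)) phi = 1e12;  // integration blow-up penalty
  return phi;
}
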