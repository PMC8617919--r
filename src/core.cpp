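// Core numerics: optimal-rotation superposition, collective-variable
// projection and its exact Cartesian gradient, the bead-chain force field,
// and the overdamped Langevin integrator.  Kept in compiled code because the
// sampler evaluates fit + projection (+ gradient at the walls) every step.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct FitState {
  arma::mat R;       // 3x3 proper rotation
  arma::rowvec Q;    // centroid of the model's fit atoms
  arma::mat fitted;  // N x 3, R %*% (r - Q) for every atom
  arma::mat V;       // right singular vectors of A
  arma::vec shat;    // singular values, last one sign-corrected
  arma::mat A;       // cross-covariance
};

// Proper rotation maximising tr(R A); equals (A^t A)^{1/2} A^{-1} when
// det(A) > 0.  Throws on (near) rank-deficient A: the fit atoms are then
// collinear and the optimal rotation is not unique.
void proper_rotation(const arma::mat& A, arma::mat& R, arma::mat& V,
                     arma::vec& shat) {
  arma::mat U;
  arma::vec s;
  if (!arma::svd(U, s, V, A))
    stop("SVD of the cross-covariance matrix failed");
  double d = arma::det(V * U.t()) < 0.0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  R = V * D * U.t();
  shat = s;
  shat(2) *= d;
  // uniqueness of the optimum needs shat_i + shat_j > 0 for all i != j
  if (shat(1) + shat(2) <= 1e-10 * (1.0 + s(0)))
    stop("degenerate superposition: fit atoms are (nearly) collinear");
}

FitState fit_state(const arma::mat& X, const arma::mat& S,
                   const arma::uvec& fidx) {
  FitState st;
  const arma::mat Xf = X.rows(fidx);
  st.Q = arma::mean(Xf, 0);
  const arma::rowvec P = arma::mean(S, 0);
  const arma::mat Yf = Xf.each_row() - st.Q;  // nfit x 3
  const arma::mat M = S.each_row() - P;       // nfit x 3
  st.A = Yf.t() * M;                          // A_ab = sum (r-Q)_a (s-P)_b
  proper_rotation(st.A, st.R, st.V, st.shat);
  st.fitted = (X.each_row() - st.Q) * st.R.t();
  return st;
}

// v_m = c_m . vec(fitted') - offset, with vec in (x1,y1,z1,x2,...) order
double project_cv(const FitState& st, const arma::vec& cvec, double offset) {
  const arma::vec f = arma::vectorise(st.fitted.t());
  return arma::dot(cvec, f) - offset;
}

// Exact gradient of the projection with respect to every Cartesian
// coordinate, including the dependence of R and Q on the fit atoms.
// Perturbation of the stationarity condition (R A symmetric) gives, for a
// perturbation dA of the cross-covariance, dR = Omega R with Omega skew and
// (in the basis V of A's right singular vectors)
//   Omega~_ij = C~_ij / (shat_i + shat_j),  C = dA' R' - R dA.
arma::mat cv_gradient(const arma::mat& X, const arma::mat& S,
                      const arma::uvec& fidx, const arma::vec& cvec) {
  const arma::uword N = X.n_rows;
  const arma::uword nfit = fidx.n_elem;
  FitState st = fit_state(X, S, fidx);
  const arma::rowvec P = arma::mean(S, 0);
  const arma::mat Mref = S.each_row() - P;          // nfit x 3
  const arma::mat Y = X.each_row() - st.Q;          // N x 3
  const arma::mat Cm = arma::reshape(cvec, 3, N).t();  // N x 3, c per atom

  arma::mat grad = Cm * st.R;                       // direct term R^t c_j
  const arma::rowvec csum = arma::sum(Cm, 0);
  const arma::rowvec qterm = (csum * st.R) / double(nfit);

  // rotation term: dv = tr(Omega G), G = R T, T = sum_i y_i c_i^t
  const arma::mat T = Y.t() * Cm;                   // 3x3
  const arma::mat Gt = st.V.t() * (st.R * T) * st.V;
  arma::mat denom(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      denom(i, j) = st.shat(i) + st.shat(j);
  const arma::mat rtil = st.V.t() * st.R;           // columns: V^t R(:,b)

  for (arma::uword k = 0; k < nfit; ++k) {
    const arma::uword j = fidx(k);
    const arma::vec mt = st.V.t() * Mref.row(k).t();  // V^t (s_j - P)
    for (int b = 0; b < 3; ++b) {
      // C = m r_b^t - r_b m^t in V basis; Omega~ = C~ / denom
      const arma::mat Ct = mt * rtil.col(b).t() - rtil.col(b) * mt.t();
      double dv = 0.0;
      for (int i = 0; i < 3; ++i)
        for (int l = 0; l < 3; ++l)
          if (i != l) dv += (Ct(i, l) / denom(i, l)) * Gt(l, i);
      grad(j, b) += dv;
    }
    grad.row(j) -= qterm;
  }
  return grad;
}

struct ToyParams {
  double bond_k, bond_b0, h, q0, w, tilt, theta0, plane_k, chiral_k;
  arma::vec bend_k;  // one constant per interior joint (length N - 2)
  arma::vec z0;      // per-bead resting z (corrugated scaffold)
};

double mode_U(double q, const ToyParams& p) {
  const double u = (q - p.q0);
  const double a = u * u - p.w * p.w;
  return p.h * a * a / (p.w * p.w * p.w * p.w) + p.tilt * u;
}

double mode_dU(double q, const ToyParams& p) {
  const double u = (q - p.q0);
  return 4.0 * p.h * u * (u * u - p.w * p.w) / (p.w * p.w * p.w * p.w) +
         p.tilt;
}

// harmonic bonds along the chain plus a double-well potential on the
// end-to-end distance; fills F with the force (-dU/dx), returns U
double toy_energy_force(const arma::mat& X, const ToyParams& p,
                        arma::mat& F) {
  const arma::uword N = X.n_rows;
  F.zeros(N, 3);
  double U = 0.0;
  for (arma::uword i = 0; i + 1 < N; ++i) {
    arma::rowvec dr = X.row(i + 1) - X.row(i);
    double d = arma::norm(dr);
    if (d < 1e-10) continue;
    double stretch = d - p.bond_b0;
    U += 0.5 * p.bond_k * stretch * stretch;
    arma::rowvec f = (p.bond_k * stretch / d) * dr;
    F.row(i) += f;
    F.row(i + 1) -= f;
  }
  // bending: U = k_i/2 (theta_i - theta0)^2 at interior bead i; joints
  // with k_i = 0 (the hinge) bend freely.  A chiral term -k_chi * s_i,
  // with s_i the normalised z-component of the joint cross product,
  // prefers one in-plane turn direction (proteins are chiral); it lifts
  // the mirror degeneracy of the hinge motion.
  for (arma::uword i = 1; i + 1 < N; ++i) {
    double kb = p.bend_k(i - 1);
    arma::rowvec u = X.row(i - 1) - X.row(i);
    arma::rowvec w = X.row(i + 1) - X.row(i);
    double nu = arma::norm(u), nw = arma::norm(w);
    if (nu < 1e-10 || nw < 1e-10) continue;
    if (kb > 0.0) {
      double ct = arma::dot(u, w) / (nu * nw);
      ct = std::max(-1.0, std::min(1.0, ct));
      double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
      double th = std::acos(ct);
      double dUdct = -kb * (th - p.theta0) / st;  // dU/dcos via dtheta/dcos
      U += 0.5 * kb * (th - p.theta0) * (th - p.theta0);
      arma::rowvec dctdu = w / (nu * nw) - ct * u / (nu * nu);
      arma::rowvec dctdw = u / (nu * nw) - ct * w / (nw * nw);
      F.row(i - 1) -= dUdct * dctdu;
      F.row(i + 1) -= dUdct * dctdw;
      F.row(i) += dUdct * (dctdu + dctdw);
    }
    if (p.chiral_k != 0.0) {
      double cz = (u(0) * w(1) - u(1) * w(0)) / (nu * nw);
      U += -p.chiral_k * cz;
      arma::rowvec dcdu = {w(1) / (nu * nw), -w(0) / (nu * nw), 0.0};
      arma::rowvec dcdw = {-u(1) / (nu * nw), u(0) / (nu * nw), 0.0};
      dcdu -= cz * u / (nu * nu);
      dcdw -= cz * w / (nw * nw);
      F.row(i - 1) += p.chiral_k * dcdu;
      F.row(i + 1) += p.chiral_k * dcdw;
      F.row(i) -= p.chiral_k * (dcdu + dcdw);
    }
  }
  // z scaffold: each bead is tethered to its resting height z0_i.  The
  // corrugated z0 pattern keeps the resting geometry three-dimensional
  // (a well-conditioned superposition target) while confining the hinge
  // motion to the xy plane, removing its azimuthal degeneracy.
  if (p.plane_k > 0.0) {
    for (arma::uword i = 0; i < N; ++i) {
      double dz = X(i, 2) - p.z0(i);
      U += 0.5 * p.plane_k * dz * dz;
      F(i, 2) -= p.plane_k * dz;
    }
  }
  arma::rowvec ee = X.row(N - 1) - X.row(0);
  double q = arma::norm(ee);
  U += mode_U(q, p);
  if (q > 1e-8) {
    arma::rowvec f = (mode_dU(q, p) / q) * ee;
    F.row(0) += f;
    F.row(N - 1) -= f;
  }
  return U;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_model(const arma::mat& X, const arma::mat& S,
                   const arma::uvec& fit_idx0) {
  FitState st = fit_state(X, S, fit_idx0);
  return List::create(_["R"] = st.R, _["Q"] = st.Q.t(),
                      _["fitted"] = st.fitted);
}

// [[Rcpp::export]]
arma::mat cpp_optimal_rotation(const arma::mat& A) {
  arma::mat R, V;
  arma::vec shat;
  proper_rotation(A, R, V, shat);
  return R;
}

// [[Rcpp::export]]
arma::mat cpp_cv_gradient(const arma::mat& X, const arma::mat& S,
                          const arma::uvec& fit_idx0, const arma::vec& cvec) {
  return cv_gradient(X, S, fit_idx0, cvec);
}

// [[Rcpp::export]]
NumericVector cpp_mode_potential(const NumericVector& q, double h,
                                 double q0, double w, double tilt) {
  ToyParams p{0, 0, h, q0, w, tilt, 0, 0, 0, arma::vec(), arma::vec()};
  NumericVector out(q.size());
  for (R_xlen_t i = 0; i < q.size(); ++i) out[i] = mode_U(q[i], p);
  return out;
}

// [[Rcpp::export]]
List cpp_toy_energy_force(const arma::mat& X, double bond_k, double bond_b0,
                          double h, double q0, double w, double tilt,
                          const arma::vec& bend_k, double theta0,
                          double plane_k, double chiral_k,
                          const arma::vec& z0) {
  ToyParams p{bond_k, bond_b0, h, q0, w, tilt, theta0, plane_k, chiral_k,
              bend_k, z0};
  arma::mat F;
  double U = toy_energy_force(X, p, F);
  return List::create(_["energy"] = U, _["force"] = F);
}

// Overdamped Langevin (Euler-Maruyama):
//   x <- x + (dt/gamma) * F + sqrt(2 kT dt / gamma) * xi
// Normal deviates come from R's RNG so runs are reproducible via set.seed().
// When a restraint is supplied, the flat-bottom force on the collective
// variables (projections onto the columns of `cvmat` after superposition on
// S) is added every step.  Beyond `wall_cap` Angstrom outside the box the
// wall continues with constant force (harmonic-then-linear): those
// configurations are excluded from all statistics by the exclusion rule,
// and the linear continuation keeps the integration stable when a start
// structure lies far outside its region.
// [[Rcpp::export]]
List cpp_langevin_run(const arma::mat& X0, int n_steps, double dt,
                      double gamma, double kT, double bond_k, double bond_b0,
                      double h, double q0, double w, double tilt,
                      const arma::vec& bend_k, double theta0, double plane_k,
                      double chiral_k, const arma::vec& z0,
                      bool has_basis, const arma::mat& cvmat,
                      const arma::vec& offsets, const arma::mat& S,
                      const arma::uvec& fit_idx0, bool has_restraint,
                      double rk, const arma::vec& vmin, const arma::vec& vmax,
                      int save_every, double blowup, double wall_cap,
                      double max_drift) {
  ToyParams p{bond_k, bond_b0, h, q0, w, tilt, theta0, plane_k, chiral_k,
              bend_k, z0};
  const arma::uword N = X0.n_rows;
  const int n_save = n_steps / save_every;
  arma::mat frames(n_save, 3 * N);
  arma::mat cvs(n_save, has_basis ? cvmat.n_cols : 1);
  IntegerVector steps(n_save);
  arma::mat X = X0, F;
  const double noise = std::sqrt(2.0 * kT * dt / gamma);
  const double scale = dt / gamma;
  int isave = 0;

  for (int t = 1; t <= n_steps; ++t) {
    toy_energy_force(X, p, F);
    arma::mat Ftot = F;
    if (has_restraint) {
      FitState st = fit_state(X, S, fit_idx0);
      for (arma::uword m = 0; m < cvmat.n_cols; ++m) {
        double v = project_cv(st, cvmat.col(m), offsets(m));
        double excess = 0.0;
        if (v < vmin(m)) excess = v - vmin(m);
        else if (v > vmax(m)) excess = v - vmax(m);
        if (excess != 0.0) {
          if (excess > wall_cap) excess = wall_cap;
          if (excess < -wall_cap) excess = -wall_cap;
          arma::mat g = cv_gradient(X, S, fit_idx0, cvmat.col(m));
          Ftot -= rk * excess * g;
        }
      }
    }
    for (arma::uword i = 0; i < N; ++i) {
      for (int a = 0; a < 3; ++a) {
        double drift = scale * Ftot(i, a);
        // drift clamp: inert in equilibrium (typical |drift| ~ 0.05 A),
        // prevents runaway during far-from-equilibrium transients
        if (drift > max_drift) drift = max_drift;
        if (drift < -max_drift) drift = -max_drift;
        X(i, a) += drift + noise * norm_rand();
      }
    }
    if (arma::abs(X).max() > blowup)
      stop("Langevin integration diverged at step %d (|coordinate| > %g)",
           t, blowup);
    if (t % save_every == 0 && isave < n_save) {
      frames.row(isave) = arma::vectorise(X.t()).t();
      if (has_basis) {
        FitState st = fit_state(X, S, fit_idx0);
        for (arma::uword m = 0; m < cvmat.n_cols; ++m)
          cvs(isave, m) = project_cv(st, cvmat.col(m), offsets(m));
      } else {
        cvs(isave, 0) = NA_REAL;
      }
      steps[isave] = t;
      ++isave;
    }
  }
  return List::create(_["frames"] = frames, _["cv"] = cvs,
                      _["steps"] = steps, _["final"] = X);
}
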