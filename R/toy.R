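#' Build the two-lobe bead-chain toy model
#'
#' A chain of `n_beads` beads joined by harmonic bonds and organised as two
#' stiff, gently curved lobes around a free hinge joint at the middle bead,
#' with a quartic double-well potential on the end-to-end distance q: wells
#' at `q0 - w` (closed hinge) and `q0 + w` (open hinge), barrier height `h`
#' at `q0`, and an optional linear tilt raising the open well by `delta_u`.
#' A corrugated z-scaffold keeps the hinge motion quasi-planar (removing
#' its azimuthal degeneracy) while leaving the resting geometry
#' three-dimensional, and a weak chiral joint term selects one in-plane
#' turn direction so the swing has a single branch — together these make
#' the well pair resolve within the leading principal components, as in
#' hinged inter-domain motion.  The initial structure is an arc whose
#' end-to-end distance sits in the closed well, with a small seeded
#' perturbation so the beads are never collinear.
#'
#' @param n_beads number of beads (>= 4); default 10.
#' @param bond_k harmonic bond constant, kcal mol^-1 A^-2; default 5.
#' @param bond_length equilibrium bond length, Angstrom; default 3.8 (a
#'   Calpha-Calpha virtual bond).
#' @param barrier_h double-well barrier height, kcal/mol; default 1.8
#'   (about 3 k_B T at 300 K).
#' @param q0 centre of the well pair, Angstrom; default 16.
#' @param w half-separation of the wells, Angstrom; default 4.
#' @param delta_u energy offset of the open well, kcal/mol; default 0.
#' @param bend_k bending constant of the lobe joints, kcal/mol on the
#'   cosine of the joint angle; default 150 (stiff lobes).
#' @param hinge bead indices whose joints bend freely; `NULL` (default)
#'   frees the middle bead.
#' @param theta0 preferred joint angle of stiff joints, radians; default
#'   8 pi / 9 (160 degrees: gently curved, non-collinear lobes).
#' @param plane_k z-scaffold constant, kcal mol^-1 A^-2; default 10.
#' @param z_amplitude corrugation amplitude of the resting heights z0
#'   (Angstrom); default 2.  A zero amplitude gives a flat slab.
#' @param chiral_k chiral joint term, kcal/mol; default 2.  Prefers one
#'   in-plane turn direction so the hinge motion has a single branch.
#' @param temperature kelvin; default 300.
#' @param seed integer seed for the initial perturbation.
#' @return list with `model` (a [ToyBeadModel-class]) and `coords`
#'   (n_beads x 3 initial coordinates).
#' @export
buildToyModel <- function(n_beads = 10L, bond_k = 5, bond_length = 3.8,
                          barrier_h = 1.8, q0 = 16, w = 4, delta_u = 0,
                          bend_k = 150, hinge = NULL, theta0 = 8 * pi / 9,
                          plane_k = 10, z_amplitude = 2, chiral_k = 2,
                          temperature = 300, seed = 1L) {
  n_beads <- as.integer(n_beads)
  if (n_beads < 4L) stop("need at least 4 beads")
  if (is.null(hinge)) hinge <- floor(n_beads / 2) + 1L
  bendk_vec <- rep(bend_k, n_beads - 2L)
  joint <- hinge[hinge >= 2L & hinge <= n_beads - 1L] - 1L
  bendk_vec[joint] <- 0
  z0 <- z_amplitude * sin(2 * pi * (seq_len(n_beads) - 1) / 4)
  model <- new("ToyBeadModel", n_beads = n_beads,
               bond_k = bond_k, bond_length = bond_length,
               mode = list(h = barrier_h, q0 = q0, w = w,
                           delta_u = delta_u),
               bend_k = bendk_vec, theta0 = theta0,
               plane_k = plane_k, z0 = z0, chiral_k = chiral_k,
               temperature = temperature)
  target <- q0 - w                      # start in the closed well
  coords <- .arcChain(n_beads, bond_length, target)
  coords[, 3] <- z0
  set.seed(as.integer(seed))
  coords <- coords + matrix(rnorm(3 * n_beads, sd = 0.05), ncol = 3)
  list(model = model, coords = coords)
}

# chain of n beads on a circular arc with bond length b and end-to-end
# distance as close to `target` as the arc geometry allows
.arcChain <- function(n, b, target) {
  target <- min(target, 0.99 * b * (n - 1))
  # chord angle theta on a circle of radius rho: b = 2 rho sin(theta/2),
  # end-to-end = 2 rho sin((n-1) theta / 2)
  f <- function(theta) b * sin((n - 1) * theta / 2) / sin(theta / 2) - target
  theta <- stats::uniroot(f, c(1e-6, 2 * pi / (n - 1) - 1e-6))$root
  rho <- b / (2 * sin(theta / 2))
  ang <- (seq_len(n) - 1) * theta
  # clockwise parametrisation: positive z cross product at every joint,
  # matching the chiral term's preferred turn direction
  cbind(rho * cos(ang), -rho * sin(ang), 0)
}

# linear tilt coefficient making U(q0 + w) - U(q0 - w) = delta_u
.modeTilt <- function(model) model@mode$delta_u / (2 * model@mode$w)

#' Toy-model potential energy and forces
#'
#' @param model a [ToyBeadModel-class].
#' @param coords n_beads x 3 coordinates.
#' @return list with `energy` (kcal/mol) and `force` (n_beads x 3,
#'   -dU/dx).
#' @export
toyEnergyForce <- function(model, coords) {
  stopifnot(is(model, "ToyBeadModel"))
  r <- cpp_toy_energy_force(as.matrix(coords), model@bond_k,
                            model@bond_length, model@mode$h, model@mode$q0,
                            model@mode$w, .modeTilt(model), model@bend_k,
                            model@theta0, model@plane_k, model@chiral_k,
                            model@z0)
  list(energy = r$energy, force = r$force)
}

#' Double-well potential on the end-to-end coordinate
#'
#' @param model a [ToyBeadModel-class].
#' @param q end-to-end distances (Angstrom).
#' @return U(q) in kcal/mol.
#' @export
modePotential <- function(model, q) {
  stopifnot(is(model, "ToyBeadModel"))
  as.numeric(cpp_mode_potential(q, model@mode$h, model@mode$q0,
                                model@mode$w, .modeTilt(model)))
}

#' Basin free-energy difference of the well coordinate by quadrature
#'
#' Integrates exp(-U(q)/kT) over each side of the barrier top; for wells of
#' equal curvature the result equals the energy offset of the wells.
#'
#' @param model a [ToyBeadModel-class].
#' @param q_split dividing point between the basins (default the well-pair
#'   centre `q0`).
#' @param q_range integration range (default `q0 +/- 3 w`).
#' @return F(extended basin) - F(compact basin) in kcal/mol.
#' @export
modeBasinDeltaF <- function(model, q_split = NULL, q_range = NULL) {
  stopifnot(is(model, "ToyBeadModel"))
  kT <- thermalEnergy(model@temperature)
  if (is.null(q_split)) q_split <- model@mode$q0
  if (is.null(q_range))
    q_range <- model@mode$q0 + c(-3, 3) * model@mode$w
  dens <- function(q) exp(-modePotential(model, q) / kT)
  za <- stats::integrate(dens, q_range[1], q_split)$value
  zb <- stats::integrate(dens, q_split, q_range[2])$value
  -kT * log(zb / za)
}

#' Overdamped Langevin sampling of the toy model
#'
#' Euler-Maruyama integration of dx = (F/gamma) dt + sqrt(2 kT dt / gamma)
#' dW at the model's temperature, with the flat-bottom collective-variable
#' restraint force added when a restraint (and basis) is supplied.  Fully
#' deterministic for a given seed.
#'
#' @param model a [ToyBeadModel-class].
#' @param start_coords n_beads x 3 starting coordinates.
#' @param n_steps number of integration steps.
#' @param restraint optional [FlatBottomRestraint-class] acting on the first
#'   `length(v_min)` components of `basis`.
#' @param basis optional [PCABasis-class]; required with a restraint, and
#'   used to record (v1, v2) for saved frames when present.
#' @param dt time step (reduced units); default 0.005, small enough for
#'   the default bond and lobe-bending stiffness.
#' @param friction friction coefficient gamma; default 1.
#' @param seed integer RNG seed.
#' @param save_every record every `save_every`-th step; default 10.
#' @param blowup error out if any |coordinate| exceeds this (default 1e4 A).
#' @param wall_cap the restraint wall is harmonic up to this many Angstrom
#'   outside the box and continues with constant force beyond (default 5).
#'   Samples out there are excluded from all statistics by the exclusion
#'   rule; the linear continuation only keeps far-from-region transients
#'   numerically stable.
#' @param max_drift clamp on the deterministic displacement per coordinate
#'   per step (Angstrom, default 0.5).  Far above the equilibrium drift
#'   (about 0.05 A at the default dt), so it only damps transients.
#' @return a [Trajectory-class].
#' @export
langevinRun <- function(model, start_coords, n_steps, restraint = NULL,
                        basis = NULL, dt = 0.005, friction = 1, seed = 1L,
                        save_every = 10L, blowup = 1e4, wall_cap = 5,
                        max_drift = 0.5) {
  stopifnot(is(model, "ToyBeadModel"))
  if (!is.null(restraint) && is.null(basis))
    stop("a restraint needs a PCA basis to define the collective variables")
  has_basis <- !is.null(basis)
  if (has_basis) {
    stopifnot(is(basis, "PCABasis"))
    ndim <- if (is.null(restraint)) 2L else length(restraint@v_min)
    cvmat <- basis@eigenvectors[, seq_len(ndim), drop = FALSE]
    offsets <- if (basis@centered)
      as.numeric(crossprod(cvmat, basis@mean_coords)) else numeric(ndim)
    S <- basis@fit_reference@ref_coords
    fidx <- basis@fit_reference@fit_indices - 1L
  } else {
    cvmat <- matrix(0, 1, 1); offsets <- 0
    S <- matrix(0, 3, 3); fidx <- 0:2
  }
  kT <- thermalEnergy(model@temperature)
  set.seed(as.integer(seed))
  res <- cpp_langevin_run(
    as.matrix(start_coords), as.integer(n_steps), dt, friction, kT,
    model@bond_k, model@bond_length, model@mode$h, model@mode$q0,
    model@mode$w, .modeTilt(model), model@bend_k, model@theta0,
    model@plane_k, model@chiral_k, model@z0, has_basis, cvmat, offsets, S,
    as.integer(fidx), !is.null(restraint),
    if (is.null(restraint)) 0 else restraint@k,
    if (is.null(restraint)) numeric(2) else restraint@v_min,
    if (is.null(restraint)) numeric(2) else restraint@v_max,
    as.integer(save_every), blowup, wall_cap, max_drift)
  cv <- res$cv
  if (!has_basis)
    cv <- matrix(NA_real_, nrow(res$frames), 2)
  new("Trajectory", frames = res$frames, cv = cv,
      steps = as.integer(res$steps), seed = as.integer(seed))
}

#' Convert toy trajectory frames to a ConformationEnsemble
#'
#' Frames become models of dummy Calpha atoms (residue numbers 1..n_beads),
#' so the structure I/O and analysis tools apply to toy output.
#'
#' @param traj a [Trajectory-class].
#' @param every keep every `every`-th saved frame (default 1).
#' @param label ensemble label.
#' @return a [ConformationEnsemble-class].
#' @export
trajectoryToEnsemble <- function(traj, every = 1L, label = "toy") {
  stopifnot(is(traj, "Trajectory"))
  keep <- seq(1L, nrow(traj@frames), by = every)
  n <- ncol(traj@frames) / 3L
  models <- lapply(keep, function(i)
    matrix(traj@frames[i, ], ncol = 3, byrow = TRUE))
  atoms <- data.frame(residue_index = seq_len(n),
                      residue_name = "GLY", atom_name = "CA",
                      element = "C", chain_id = "A")
  conformationEnsemble(models, atoms, label = label)
}

#' Ground-truth free-energy landscape by long unbiased sampling
#'
#' Runs a long unrestrained Langevin trajectory, projects every saved frame
#' onto the basis, and Boltzmann-inverts the (v1, v2) histogram:
#' F = -kT ln rho, min-shifted to 0.  Serves as the independent reference
#' the stitched landscape is validated against.
#'
#' @param model a [ToyBeadModel-class].
#' @param start_coords starting coordinates.
#' @param basis a [PCABasis-class].
#' @param v1_edges,v2_edges bin boundaries of the requested grid.
#' @param n_steps unbiased run length (default 2e6).
#' @param min_count bins with fewer raw samples are masked (default 1).
#' @param warn_empty warn when requested bins end up masked (default TRUE).
#' @inheritParams langevinRun
#' @return a [FELGrid-class]; bins with insufficient samples are masked.
#' @export
referenceFelOracle <- function(model, start_coords, basis, v1_edges,
                               v2_edges, n_steps = 2e6, dt = 0.005,
                               friction = 1, seed = 99L, save_every = 10L,
                               min_count = 1, warn_empty = TRUE) {
  traj <- langevinRun(model, start_coords, n_steps, restraint = NULL,
                      basis = basis, dt = dt, friction = friction,
                      seed = seed, save_every = save_every)
  fel <- binFel(traj@cv, v1_edges, v2_edges,
                kT = thermalEnergy(model@temperature),
                min_count = min_count)
  if (warn_empty && any(fel@mask))
    warning(sprintf("%d of %d requested bins have too few samples and are masked",
                    sum(fel@mask), length(fel@mask)))
  fel
}

#' Boltzmann inversion of a (weighted) 2D histogram
#'
#' @param cv two-column matrix of (v1, v2) samples.
#' @param v1_edges,v2_edges bin boundaries.
#' @param kT thermal energy (kcal/mol).
#' @param weights optional per-sample weights (default 1).
#' @param min_count bins whose weighted count is below this are masked.
#' @return a [FELGrid-class].
#' @export
binFel <- function(cv, v1_edges, v2_edges, kT, weights = NULL,
                   min_count = .Machine$double.eps) {
  cv <- as.matrix(cv)
  if (is.null(weights)) weights <- rep(1, nrow(cv))
  n1 <- length(v1_edges) - 1L; n2 <- length(v2_edges) - 1L
  i1 <- findInterval(cv[, 1], v1_edges, rightmost.closed = TRUE)
  i2 <- findInterval(cv[, 2], v2_edges, rightmost.closed = TRUE)
  ok <- i1 >= 1L & i1 <= n1 & i2 >= 1L & i2 <= n2
  counts <- matrix(0, n1, n2)
  if (any(ok)) {
    tab <- tapply(weights[ok], list(factor(i1[ok], levels = seq_len(n1)),
                                    factor(i2[ok], levels = seq_len(n2))),
                  sum)
    tab[is.na(tab)] <- 0
    counts <- matrix(tab, n1, n2)
  }
  total <- sum(counts)
  if (total <= 0) stop("no samples fall inside the requested grid")
  mask <- counts < min_count | counts <= 0
  F <- matrix(NA_real_, n1, n2)
  F[!mask] <- -kT * log(counts[!mask] / total)
  F[!mask] <- F[!mask] - min(F[!mask])
  new("FELGrid", v1_edges = as.numeric(v1_edges),
      v2_edges = as.numeric(v2_edges), F = F, mask = mask,
      counts = counts, kT = kT, total_weighted_count = total)
}
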