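# Shared fixture builders: everything is generated in code at test time.

ca_atoms <- function(n) {
  data.frame(residue_index = seq_len(n), residue_name = "GLY",
             atom_name = "CA", element = "C", chain_id = "A")
}

# random Calpha-only ensemble around a common core
random_ensemble <- function(n_atoms = 10, n_models = 5, sd = 0.5,
                            seed = 1) {
  set.seed(seed)
  core <- matrix(rnorm(3 * n_atoms, sd = 4), n_atoms, 3)
  models <- lapply(seq_len(n_models), function(i)
    core + matrix(rnorm(3 * n_atoms, sd = sd), n_atoms, 3))
  conformationEnsemble(models, ca_atoms(n_atoms))
}

# rotation matrix about z by angle theta
rot_z <- function(theta)
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3)

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  cbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
      2 * (q[2] * q[4] - q[1] * q[3])),
    c(2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] + q[1] * q[2])),
    c(2 * (q[2] * q[4] + q[1] * q[3]), 2 * (q[3] * q[4] - q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)))
}

# ensemble whose only variation is a displacement mode on NON-fit atoms,
# so the superposition is constant across models and projections are an
# exact linear map; returns the known per-model amplitudes
mode_ensemble <- function(amplitudes, n_atoms = 10, n_fit = 5, seed = 2) {
  set.seed(seed)
  core <- matrix(rnorm(3 * n_atoms, sd = 4), n_atoms, 3)
  mode <- matrix(0, n_atoms, 3)
  mode[(n_fit + 1):n_atoms, ] <- matrix(rnorm(3 * (n_atoms - n_fit)),
                                        ncol = 3)
  mode <- mode / sqrt(sum(mode^2))
  models <- lapply(amplitudes, function(a) core + a * mode)
  list(ens = conformationEnsemble(models, ca_atoms(n_atoms)),
       core = core, mode = mode, fit_idx = seq_len(n_fit))
}

# FELGrid built directly from a free-energy matrix (NA = masked)
fel_from_matrix <- function(F, v1_edges, v2_edges, kT = 0.6) {
  mask <- is.na(F)
  if (any(!mask)) F[!mask] <- F[!mask] - min(F[!mask])
  counts <- matrix(0, nrow(F), ncol(F))
  counts[!mask] <- 1
  new("FELGrid", v1_edges = v1_edges, v2_edges = v2_edges, F = F,
      mask = mask, counts = counts, kT = kT,
      total_weighted_count = sum(counts))
}

# central finite-difference gradient of projectCV
fd_cv_gradient <- function(X, basis, m, h = 1e-4) {
  g <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) {
    for (a in 1:3) {
      Xp <- X; Xp[i, a] <- Xp[i, a] + h
      Xm <- X; Xm[i, a] <- Xm[i, a] - h
      g[i, a] <- (projectCV(Xp, basis, m)[1] - projectCV(Xm, basis, m)[1]) /
        (2 * h)
    }
  }
  g
}

# small basis over a random ensemble, for gradient/restraint tests
small_basis <- function(n_atoms = 6, n_models = 8, seed = 7) {
  ens <- random_ensemble(n_atoms, n_models, sd = 1, seed = seed)
  ref <- fitReference(modelCoords(ens, 1), seq_len(n_atoms))
  buildPcaBasis(ens, ref)
}
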