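#' Flat-bottom restraint energy
#'
#' Per CV dimension m: k/2 (v_min_m - v_m)^2 below the box,
#' 0 for v_min_m <= v_m <= v_max_m, k/2 (v_m - v_max_m)^2 above; summed
#' over dimensions.  Continuous and once-differentiable at the edges.
#'
#' @param v numeric CV value, one entry per restrained dimension.
#' @param restraint a [FlatBottomRestraint-class].
#' @return energy in kcal/mol.
#' @export
flatBottomEnergy <- function(v, restraint) {
  stopifnot(is(restraint, "FlatBottomRestraint"),
            length(v) == length(restraint@v_min))
  below <- pmin(v - restraint@v_min, 0)
  above <- pmax(v - restraint@v_max, 0)
  0.5 * restraint@k * sum(below^2 + above^2)
}

#' Cartesian gradient of a collective variable
#'
#' Exact gradient of [projectCV()] with respect to every atomic coordinate,
#' including the dependence of the superposition rotation R and centroid Q
#' on the fit atoms (obtained by differentiating the stationarity condition
#' of the optimal rotation).  The gradient rows sum to zero: the fitted
#' projection is translation-invariant.
#'
#' @param model_coords N x 3 coordinate matrix.
#' @param basis a [PCABasis-class].
#' @param m component index (scalar).
#' @return N x 3 matrix of d v_m / d r_i.
#' @export
cvGradient <- function(model_coords, basis, m) {
  stopifnot(is(basis, "PCABasis"), length(m) == 1L)
  if (m < 1L || m > ncol(basis@eigenvectors))
    stop("component index out of range")
  X <- as.matrix(model_coords)
  ref <- basis@fit_reference
  if (max(ref@fit_indices) > nrow(X))
    stop("model does not contain all fit atoms")
  cpp_cv_gradient(X, ref@ref_coords, ref@fit_indices - 1L,
                  basis@eigenvectors[, m])
}

#' Flat-bottom restraint force on every atom
#'
#' -grad phi: zero while the CV lies inside the box; outside, the wall force
#' -k (v_m - edge) grad v_m for each violated dimension, summed.
#'
#' @param model_coords N x 3 coordinate matrix.
#' @param basis a [PCABasis-class]; component m of the restraint acts on
#'   eigenvector m.
#' @param restraint a [FlatBottomRestraint-class].
#' @return N x 3 force matrix (kcal mol^-1 A^-1).
#' @export
flatBottomForce <- function(model_coords, basis, restraint) {
  stopifnot(is(basis, "PCABasis"), is(restraint, "FlatBottomRestraint"))
  ndim <- length(restraint@v_min)
  v <- projectCV(model_coords, basis, seq_len(ndim))
  force <- matrix(0, nrow = nrow(as.matrix(model_coords)), ncol = 3)
  for (m in seq_len(ndim)) {
    excess <- if (v[m] < restraint@v_min[m]) v[m] - restraint@v_min[m]
              else if (v[m] > restraint@v_max[m]) v[m] - restraint@v_max[m]
              else 0
    if (excess != 0)
      force <- force - restraint@k * excess * cvGradient(model_coords,
                                                         basis, m)
  }
  force
}
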