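#' Cross-covariance between a model and the reference sub-structure
#'
#' A_ab = sum_nu (r_nu - Q)_a (s_nu - P)_b over the fit atoms, where Q and P
#' are the centroids of the model's and the reference's fit atoms.  The
#' optimal superposition rotation is a function of this matrix alone.
#'
#' @param model_fit_coords n_fit x 3 coordinates of the model's fit atoms.
#' @param ref a [FitReference-class] with the same number of fit atoms.
#' @return a 3 x 3 matrix.
#' @export
crossCovariance <- function(model_fit_coords, ref) {
  stopifnot(is(ref, "FitReference"))
  r <- as.matrix(model_fit_coords)
  if (nrow(r) != nrow(ref@ref_coords))
    stop("model and reference must have the same number of fit atoms")
  if (nrow(r) < 3L) stop("need at least 3 fit atoms")
  Q <- colMeans(r)
  crossprod(sweep(r, 2, Q), sweep(ref@ref_coords, 2, ref@centroid))
}

#' Optimal proper rotation from a cross-covariance matrix
#'
#' Returns the rotation R minimising the fit-atom RMSD, computed by singular
#' value decomposition with a determinant correction so that det(R) = +1
#' even for reflected configurations.  When det(A) > 0 this equals
#' (A^t A)^(1/2) A^(-1).
#'
#' @param A 3 x 3 cross-covariance matrix (see [crossCovariance()]).
#' @return a 3 x 3 proper rotation matrix.
#' @export
optimalRotation <- function(A) {
  A <- as.matrix(A)
  stopifnot(all(dim(A) == c(3L, 3L)))
  cpp_optimal_rotation(A)
}

#' Superpose a model onto the fit reference
#'
#' The fit atoms define the centroid Q and the optimal rotation R; the
#' transformation r' = R (r - Q) is then applied to every atom of the model.
#'
#' @param model_coords N x 3 coordinates of the full model.
#' @param ref a [FitReference-class]; its `fit_indices` must be valid
#'   indices into `model_coords`.
#' @return list with elements `R` (3 x 3 rotation), `Q` (length-3 centroid)
#'   and `fitted` (N x 3 fitted coordinates).
#' @export
fitModel <- function(model_coords, ref) {
  stopifnot(is(ref, "FitReference"))
  X <- as.matrix(model_coords)
  if (max(ref@fit_indices) > nrow(X))
    stop("model does not contain all fit atoms")
  res <- cpp_fit_model(X, ref@ref_coords, ref@fit_indices - 1L)
  list(R = res$R, Q = as.numeric(res$Q), fitted = res$fitted)
}

# flatten an N x 3 coordinate matrix to (x1, y1, z1, x2, ...) order
.flattenCoords <- function(m) as.vector(t(m))
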