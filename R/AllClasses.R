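#' Multi-model structure ensemble
#'
#' Ordered coordinate sets sharing one atom table.  Coordinates are in
#' Angstrom; every model must have the same atoms in the same order.
#'
#' @slot models list of N_atoms x 3 numeric matrices (Angstrom).
#' @slot atoms data.frame with columns `residue_index` (1-based),
#'   `residue_name`, `atom_name`, `element`, `chain_id`.
#' @slot label free-text description.
#' @export
setClass("ConformationEnsemble",
  representation(models = "list", atoms = "data.frame", label = "character"))

setValidity("ConformationEnsemble", function(object) {
  if (length(object@models) == 0L) return("ensemble has no models")
  na <- nrow(object@atoms)
  for (i in seq_along(object@models)) {
    m <- object@models[[i]]
    if (!is.matrix(m) || ncol(m) != 3L)
      return(sprintf("model %d is not an N x 3 matrix", i))
    if (nrow(m) != na)
      return(sprintf("model %d has %d atoms, atom table has %d",
                     i, nrow(m), na))
    if (!all(is.finite(m)))
      return(sprintf("model %d contains non-finite coordinates", i))
  }
  need <- c("residue_index", "residue_name", "atom_name", "element",
            "chain_id")
  if (!all(need %in% names(object@atoms)))
    return("atom table is missing required columns")
  if (any(object@atoms$residue_index < 1L))
    return("residue_index must be >= 1")
  if (any(!nzchar(object@atoms$atom_name)))
    return("atom_name must be non-empty")
  TRUE
})

#' Construct a ConformationEnsemble
#'
#' @param models list of N x 3 coordinate matrices (Angstrom).
#' @param atoms atom metadata data.frame (see class slots).
#' @param label free-text label.
#' @return a [ConformationEnsemble-class] object.
#' @export
conformationEnsemble <- function(models, atoms, label = "") {
  new("ConformationEnsemble", models = models,
      atoms = as.data.frame(atoms), label = label)
}

#' @describeIn ConformationEnsemble-class number of models
#' @param x,object a `ConformationEnsemble`.
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))
#' @rdname ConformationEnsemble-class
#' @export
setMethod("nModels", "ConformationEnsemble", function(x) length(x@models))

#' @describeIn ConformationEnsemble-class number of atoms per model
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname ConformationEnsemble-class
#' @export
setMethod("nAtoms", "ConformationEnsemble", function(x) nrow(x@atoms))

#' @describeIn ConformationEnsemble-class coordinates of model `i`
#' @param i model index.
#' @export
modelCoords <- function(x, i) {
  stopifnot(is(x, "ConformationEnsemble"))
  if (i < 1L || i > nModels(x)) stop("model index out of range")
  x@models[[i]]
}

#' @describeIn ConformationEnsemble-class atom metadata table
#' @export
atomTable <- function(x) {
  stopifnot(is(x, "ConformationEnsemble"))
  x@atoms
}

setMethod("show", "ConformationEnsemble", function(object) {
  cat(sprintf("ConformationEnsemble '%s': %d models x %d atoms, residues %d-%d\n",
              object@label, nModels(object), nAtoms(object),
              min(object@atoms$residue_index),
              max(object@atoms$residue_index)))
})

#' Superposition reference
#'
#' The fixed sub-structure that every model is superposed onto: the selected
#' fit-atom coordinates `s_nu`, their indices into the full atom list, and
#' their centroid `P`.
#'
#' @slot ref_coords n_fit x 3 matrix of fit-atom coordinates (Angstrom).
#' @slot fit_indices integer indices of the fit atoms in the full model.
#' @slot centroid length-3 centroid of `ref_coords`.
#' @export
setClass("FitReference",
  representation(ref_coords = "matrix", fit_indices = "integer",
                 centroid = "numeric"))

setValidity("FitReference", function(object) {
  if (length(object@fit_indices) < 3L) return("need at least 3 fit atoms")
  if (nrow(object@ref_coords) != length(object@fit_indices))
    return("ref_coords rows must match fit_indices")
  if (max(abs(colMeans(object@ref_coords) - object@centroid)) > 1e-8)
    return("centroid does not equal the mean of ref_coords")
  TRUE
})

#' Build a superposition reference from a coordinate set
#'
#' @param coords full N x 3 coordinate matrix of the reference model.
#' @param fit_indices atom indices (into `coords`) defining the fit
#'   sub-structure, e.g. the Calpha atoms of one lobe.
#' @return a [FitReference-class].
#' @export
fitReference <- function(coords, fit_indices) {
  fit_indices <- as.integer(fit_indices)
  if (length(fit_indices) < 3L) stop("need at least 3 fit atoms")
  if (any(fit_indices < 1L) || any(fit_indices > nrow(coords)))
    stop("fit_indices out of range")
  rc <- coords[fit_indices, , drop = FALSE]
  new("FitReference", ref_coords = rc, fit_indices = fit_indices,
      centroid = colMeans(rc))
}

setMethod("show", "FitReference", function(object) {
  cat(sprintf("FitReference: %d fit atoms, centroid (%.2f, %.2f, %.2f) A\n",
              length(object@fit_indices), object@centroid[1],
              object@centroid[2], object@centroid[3]))
})

#' Principal-component basis of the fitted ensemble
#'
#' Eigen-decomposition of the covariance of superposed coordinates.  The
#' collective variable v_n is the projection of a superposed structure onto
#' eigenvector c_n, by default after subtracting the ensemble mean.
#'
#' @slot mean_coords length-3N ensemble mean of fitted coordinates,
#'   (x1, y1, z1, x2, ...) ordering.
#' @slot eigenvectors 3N x K orthonormal matrix, columns c_n.
#' @slot eigenvalues length-K non-negative, descending (Angstrom^2).
#' @slot fit_reference the [FitReference-class] the basis was built with.
#' @slot centered if `TRUE` (default) projections subtract `mean_coords`.
#' @export
setClass("PCABasis",
  representation(mean_coords = "numeric", eigenvectors = "matrix",
                 eigenvalues = "numeric", fit_reference = "FitReference",
                 centered = "logical"))

setValidity("PCABasis", function(object) {
  if (nrow(object@eigenvectors) != length(object@mean_coords))
    return("eigenvector length must match mean_coords")
  if (ncol(object@eigenvectors) != length(object@eigenvalues))
    return("one eigenvalue per eigenvector required")
  if (any(object@eigenvalues < -1e-10)) return("negative eigenvalue")
  if (is.unsorted(rev(object@eigenvalues))) return("eigenvalues not descending")
  g <- crossprod(object@eigenvectors)
  if (max(abs(g - diag(ncol(g)))) > 1e-8)
    return("eigenvectors not orthonormal")
  TRUE
})

setMethod("show", "PCABasis", function(object) {
  k <- length(object@eigenvalues)
  tot <- sum(object@eigenvalues)
  top2 <- if (k >= 2 && tot > 0) sum(object@eigenvalues[1:2]) / tot else NA
  cat(sprintf("PCABasis: %d coordinates, %d components, lambda1 = %.3g A^2",
              length(object@mean_coords), k, object@eigenvalues[1]))
  if (!is.na(top2)) cat(sprintf(", first two = %.1f%% of variance", 100 * top2))
  cat("\n")
})

#' @describeIn PCABasis-class eigenvalues lambda_n (Angstrom^2)
#' @param x a `PCABasis`.
#' @export
basisEigenvalues <- function(x) { stopifnot(is(x, "PCABasis")); x@eigenvalues }

#' @describeIn PCABasis-class eigenvector matrix (3N x K, columns c_n)
#' @export
basisEigenvectors <- function(x) { stopifnot(is(x, "PCABasis")); x@eigenvectors }

#' Flat-bottom restraint on the collective variables
#'
#' Zero inside `[v_min, v_max]` per dimension, half-harmonic walls outside:
#' phi(v_m) = k/2 (v_m - edge)^2 beyond either edge, summed over dimensions.
#'
#' @slot k spring constant (kcal mol^-1 A^-2).
#' @slot v_min,v_max lower/upper edges per CV dimension (Angstrom).
#' @export
setClass("FlatBottomRestraint",
  representation(k = "numeric", v_min = "numeric", v_max = "numeric"))

setValidity("FlatBottomRestraint", function(object) {
  if (object@k < 0) return("spring constant must be >= 0")
  if (length(object@v_min) != length(object@v_max))
    return("v_min and v_max must have equal length")
  if (any(object@v_min > object@v_max)) return("v_min must be <= v_max")
  TRUE
})

#' Construct a flat-bottom restraint
#'
#' @param k spring constant in kcal mol^-1 A^-2 (default 0.048, an
#'   appropriate scale for protein-sized principal-component amplitudes).
#' @param v_min,v_max numeric vectors, one entry per restrained CV.
#' @return a [FlatBottomRestraint-class].
#' @export
flatBottomRestraint <- function(k = 0.048, v_min, v_max) {
  new("FlatBottomRestraint", k = k, v_min = as.numeric(v_min),
      v_max = as.numeric(v_max))
}

setMethod("show", "FlatBottomRestraint", function(object) {
  cat(sprintf("FlatBottomRestraint: k = %g kcal/mol/A^2, box [%s] x [%s] A\n",
              object@k, paste(signif(object@v_min, 4), collapse = ", "),
              paste(signif(object@v_max, 4), collapse = ", ")))
})

#' Region layout on the collective-variable plane
#'
#' Disjoint small areas tiling the CV domain plus the enlarged, overlapping
#' sampling regions actually simulated, and their adjacency.
#'
#' @slot small_areas n x 4 matrix, columns v1_min, v1_max, v2_min, v2_max.
#' @slot sampling_regions n x 4 matrix, small areas grown by `margin` on
#'   every edge interior to the domain.
#' @slot margin overlap margin (Angstrom).
#' @slot domain length-4 overall rectangle.
#' @slot adjacency m x 2 matrix of region index pairs (i < j) whose sampling
#'   rectangles intersect (edge and diagonal neighbours).
#' @export
setClass("RegionGrid",
  representation(small_areas = "matrix", sampling_regions = "matrix",
                 margin = "numeric", domain = "numeric",
                 adjacency = "matrix"))

setValidity("RegionGrid", function(object) {
  sa <- object@small_areas; sr <- object@sampling_regions
  if (ncol(sa) != 4L || ncol(sr) != 4L) return("rectangles need 4 columns")
  if (nrow(sa) != nrow(sr)) return("one sampling region per small area")
  if (any(sr[, 1] > sa[, 1] + 1e-9) || any(sr[, 2] < sa[, 2] - 1e-9) ||
      any(sr[, 3] > sa[, 3] + 1e-9) || any(sr[, 4] < sa[, 4] - 1e-9))
    return("each sampling region must contain its small area")
  TRUE
})

#' @describeIn RegionGrid-class number of regions
#' @param x a `RegionGrid`.
#' @export
nRegions <- function(x) { stopifnot(is(x, "RegionGrid")); nrow(x@small_areas) }

#' @describeIn RegionGrid-class small-area rectangles (n x 4)
#' @export
smallAreas <- function(x) { stopifnot(is(x, "RegionGrid")); x@small_areas }

#' @describeIn RegionGrid-class sampling-region rectangles (n x 4)
#' @export
samplingRegions <- function(x) {
  stopifnot(is(x, "RegionGrid")); x@sampling_regions
}

setMethod("show", "RegionGrid", function(object) {
  cat(sprintf(
    "RegionGrid: %d small areas, margin %g A, %d adjacent pairs, domain [%g, %g] x [%g, %g] A\n",
    nrow(object@small_areas), object@margin, nrow(object@adjacency),
    object@domain[1], object@domain[2], object@domain[3], object@domain[4]))
})

#' Per-region log-weights
#'
#' Log-scale factors W_i equalising sample densities between overlapping
#' regions, propagated from the seed region (W = 0) over usable overlap
#' edges.
#'
#' @slot W numeric log-weight per region (NA for unpopulated regions).
#' @slot linked logical, whether the region was reached from the seed.
#' @slot seed_region index of the seed region.
#' @slot n_edges_used number of overlap edges incident to each region that
#'   carried positive counts on both sides.
#' @export
setClass("WeightTable",
  representation(W = "numeric", linked = "logical", seed_region = "integer",
                 n_edges_used = "integer"))

setValidity("WeightTable", function(object) {
  s <- object@seed_region
  if (s < 1L || s > length(object@W)) return("seed_region out of range")
  TRUE
})

setMethod("show", "WeightTable", function(object) {
  cat(sprintf("WeightTable: %d regions (%d linked), seed = %d, W range [%.3g, %.3g]\n",
              length(object@W), sum(object@linked), object@seed_region,
              min(object@W, na.rm = TRUE), max(object@W, na.rm = TRUE)))
})

#' @describeIn WeightTable-class log-weights W_i
#' @param x a `WeightTable`.
#' @export
regionWeights <- function(x) { stopifnot(is(x, "WeightTable")); x@W }

#' Binned free-energy surface
#'
#' F(v1, v2) on a rectangular bin grid, with empty bins masked.  F is
#' min-shifted so the lowest populated bin is 0.
#'
#' @slot v1_edges,v2_edges bin boundaries (Angstrom).
#' @slot F free energy per bin (kcal/mol), `NA` on masked bins.
#' @slot mask logical matrix, `TRUE` where no samples fell.
#' @slot counts effective (multiplicity-corrected, weighted) counts per bin.
#' @slot kT thermal energy used (kcal/mol).
#' @slot total_weighted_count normalisation record.
#' @export
setClass("FELGrid",
  representation(v1_edges = "numeric", v2_edges = "numeric", F = "matrix",
                 mask = "matrix", counts = "matrix", kT = "numeric",
                 total_weighted_count = "numeric"))

setValidity("FELGrid", function(object) {
  n1 <- length(object@v1_edges) - 1L; n2 <- length(object@v2_edges) - 1L
  if (any(dim(object@F) != c(n1, n2))) return("F dims must match bin edges")
  if (any(dim(object@mask) != c(n1, n2))) return("mask dims must match F")
  if (object@kT <= 0) return("kT must be positive")
  vals <- object@F[!object@mask]
  if (length(vals) && (any(!is.finite(vals)) || min(vals) < -1e-8))
    return("unmasked F must be finite with minimum 0")
  TRUE
})

setMethod("show", "FELGrid", function(object) {
  vals <- object@F[!object@mask]
  cat(sprintf("FELGrid: %d x %d bins (%d populated), kT = %.3g kcal/mol, F up to %.2f kcal/mol\n",
              nrow(object@F), ncol(object@F), length(vals), object@kT,
              if (length(vals)) max(vals) else NA_real_))
})

#' @describeIn FELGrid-class free-energy matrix (kcal/mol, NA = masked)
#' @param x a `FELGrid`.
#' @export
felMatrix <- function(x) { stopifnot(is(x, "FELGrid")); x@F }

#' @describeIn FELGrid-class bin-centre vectors, list(v1, v2)
#' @export
felBinCenters <- function(x) {
  stopifnot(is(x, "FELGrid"))
  list(v1 = (head(x@v1_edges, -1) + x@v1_edges[-1]) / 2,
       v2 = (head(x@v2_edges, -1) + x@v2_edges[-1]) / 2)
}

#' Bead-chain toy model
#'
#' A two-lobe bead chain emulating hinged domain motion: harmonic bonds,
#' stiff bending inside the two lobes, free joints at the hinge, a quartic
#' double-well potential on the end-to-end distance (compact vs extended
#' lobe arrangement), and a weak slab confinement on z that removes the
#' azimuthal degeneracy of the hinge motion so the well pair maps onto a
#' single principal component.  Its equilibrium distribution is known well
#' enough (by long unbiased sampling or quadrature over the well
#' coordinate) to serve as ground truth for the stitched landscape.
#'
#' @slot n_beads number of beads (>= 4).
#' @slot bond_k harmonic bond constant (kcal mol^-1 A^-2).
#' @slot bond_length equilibrium bond length (Angstrom).
#' @slot mode list with `h` (barrier height, kcal/mol), `q0` (well-pair
#'   centre, A), `w` (half-separation of the minima, A), `delta_u`
#'   (energy offset of the far well, kcal/mol) for the quartic double well
#'   on the end-to-end distance.
#' @slot bend_k per-joint bending constants (length `n_beads - 2`, kcal/mol
#'   on the cosine of the joint angle); zero entries are the free hinge.
#' @slot theta0 preferred joint angle at stiff joints (radians).
#' @slot plane_k z-scaffold constant (kcal mol^-1 A^-2).
#' @slot z0 per-bead resting z (Angstrom); the corrugation keeps the
#'   resting geometry three-dimensional so superposition is
#'   well-conditioned, while confining the hinge motion to the xy plane.
#' @slot chiral_k strength of the chiral joint term (kcal/mol) preferring
#'   one in-plane turn direction; lifts the mirror degeneracy of the hinge.
#' @slot temperature kelvin.
#' @export
setClass("ToyBeadModel",
  representation(n_beads = "integer", bond_k = "numeric",
                 bond_length = "numeric", mode = "list",
                 bend_k = "numeric", theta0 = "numeric",
                 plane_k = "numeric", z0 = "numeric",
                 chiral_k = "numeric", temperature = "numeric"))

setValidity("ToyBeadModel", function(object) {
  if (object@n_beads < 4L) return("need at least 4 beads")
  if (object@temperature <= 0) return("temperature must be positive")
  m <- object@mode
  if (!all(c("h", "q0", "w", "delta_u") %in% names(m)))
    return("mode potential needs h, q0, w, delta_u")
  if (m$h < 0) return("mode barrier h < 0 gives an unbounded potential")
  if (m$w <= 0) return("mode half-separation w must be positive")
  if (object@bond_k <= 0) return("bond_k must be positive")
  if (length(object@bend_k) != object@n_beads - 2L)
    return("bend_k needs one constant per interior joint")
  if (any(object@bend_k < 0) || object@plane_k < 0)
    return("bend_k and plane_k must be non-negative")
  if (object@theta0 < 0 || object@theta0 > pi)
    return("theta0 must lie in [0, pi]")
  if (length(object@z0) != object@n_beads)
    return("z0 needs one resting height per bead")
  TRUE
})

setMethod("show", "ToyBeadModel", function(object) {
  cat(sprintf(
    "ToyBeadModel: %d beads, bonds k = %g (b0 = %g A), %d free hinge joint(s), slab k = %g, wells at q = %g +/- %g A (barrier %g kcal/mol, offset %g), T = %g K\n",
    object@n_beads, object@bond_k, object@bond_length,
    sum(object@bend_k == 0), object@plane_k, object@mode$q0,
    object@mode$w, object@mode$h, object@mode$delta_u, object@temperature))
})

#' Sampled trajectory
#'
#' Frames and collective-variable values recorded during a Langevin run.
#'
#' @slot frames n_save x 3N coordinate matrix, (x1, y1, z1, ...) per row.
#' @slot cv n_save x 2 matrix of (v1, v2), or NA when no basis was supplied.
#' @slot steps integer step index of each saved frame.
#' @slot seed RNG seed the run was started with.
#' @export
setClass("Trajectory",
  representation(frames = "matrix", cv = "matrix", steps = "integer",
                 seed = "integer"))

setValidity("Trajectory", function(object) {
  if (nrow(object@frames) != nrow(object@cv))
    return("one CV row per frame required")
  if (nrow(object@frames) != length(object@steps))
    return("one step index per frame required")
  TRUE
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames of %d coordinates, seed %d\n",
              nrow(object@frames), ncol(object@frames), object@seed))
})

#' @describeIn Trajectory-class (v1, v2) per saved frame
#' @param x a `Trajectory`.
#' @export
cvSeries <- function(x) { stopifnot(is(x, "Trajectory")); x@cv }

#' @describeIn Trajectory-class saved frames as an n_save x 3N matrix
#' @export
trajectoryFrames <- function(x) { stopifnot(is(x, "Trajectory")); x@frames }

#' Named group of residue contact pairs
#'
#' @slot label group name (e.g. "C1").
#' @slot pairs m x 2 matrix of 1-based residue index pairs.
#' @export
setClass("ContactGroup",
  representation(label = "character", pairs = "matrix"))

setValidity("ContactGroup", function(object) {
  if (nrow(object@pairs) == 0L) return("contact group needs >= 1 pair")
  if (any(object@pairs[, 1] == object@pairs[, 2]))
    return("a residue cannot contact itself")
  TRUE
})

#' Construct a contact group
#'
#' @param label group name.
#' @param pairs two-column matrix (or list of length-2 vectors) of residue
#'   index pairs.
#' @return a [ContactGroup-class].
#' @export
contactGroup <- function(label, pairs) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  new("ContactGroup", label = label, pairs = pairs)
}

setMethod("show", "ContactGroup", function(object) {
  cat(sprintf("ContactGroup '%s': %d residue pairs\n", object@label,
              nrow(object@pairs)))
})
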