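#' Build the principal-component basis of a fitted ensemble
#'
#' Every model is superposed onto the reference sub-structure (see
#' [fitModel()]); the covariance of the fitted coordinates over the ensemble
#' (ensemble-average convention, denominator M) is then diagonalised.
#' Eigenpairs are sorted by descending eigenvalue (ties keep their original
#' order) and each eigenvector's sign is fixed by requiring its
#' largest-magnitude coordinate to be positive, so the axes are
#' deterministic across runs.
#'
#' @param ens a [ConformationEnsemble-class] with at least 2 models.
#' @param ref a [FitReference-class].
#' @param centered if `TRUE` (default), projections subtract the ensemble
#'   mean so the training set has mean-zero collective variables; `FALSE`
#'   reproduces uncentered absolute axes (a constant offset).
#' @return a [PCABasis-class].
#' @export
buildPcaBasis <- function(ens, ref, centered = TRUE) {
  stopifnot(is(ens, "ConformationEnsemble"), is(ref, "FitReference"))
  M <- nModels(ens)
  if (M < 2L) stop("PCA needs at least 2 models")
  fitted <- t(vapply(ens@models,
                     function(m) .flattenCoords(fitModel(m, ref)$fitted),
                     numeric(3L * nAtoms(ens))))
  mu <- colMeans(fitted)
  dev <- sweep(fitted, 2, mu)
  covm <- crossprod(dev) / M          # ensemble average, denominator M
  eig <- eigen(covm, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  vec <- eig$vectors
  for (k in seq_len(ncol(vec))) {     # deterministic sign
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  new("PCABasis", mean_coords = mu, eigenvectors = vec,
      eigenvalues = lambda, fit_reference = ref, centered = centered)
}

#' Project a structure onto principal components
#'
#' v_n = c_n . (X' - mean), where X' is the model superposed onto the
#' basis's fit reference.  With an uncentered basis the mean is not
#' subtracted.
#'
#' @param model_coords N x 3 coordinates, or a [Trajectory-class] frame
#'   reshaped to N x 3.
#' @param basis a [PCABasis-class].
#' @param n component index or vector of indices (default `1:2`).
#' @return numeric vector of projections (Angstrom), one per entry of `n`.
#' @export
projectCV <- function(model_coords, basis, n = 1:2) {
  stopifnot(is(basis, "PCABasis"))
  if (any(n < 1L) || any(n > ncol(basis@eigenvectors)))
    stop("component index out of range")
  fitted <- fitModel(model_coords, basis@fit_reference)$fitted
  x <- .flattenCoords(fitted)
  if (basis@centered) x <- x - basis@mean_coords
  as.numeric(crossprod(basis@eigenvectors[, n, drop = FALSE], x))
}

#' Project every model of an ensemble
#'
#' @inheritParams projectCV
#' @param ens a [ConformationEnsemble-class].
#' @return matrix with one row per model, one column per component.
#' @export
projectEnsemble <- function(ens, basis, n = 1:2) {
  stopifnot(is(ens, "ConformationEnsemble"))
  v <- vapply(ens@models, function(m) projectCV(m, basis, n),
              numeric(length(n)))
  if (length(n) == 1L) matrix(v, ncol = 1) else t(v)
}

#' Cumulative proportion of variance
#'
#' @param basis a [PCABasis-class].
#' @param k number of leading components.
#' @return sum(lambda_1..k) / sum(lambda), in `[0, 1]`.
#' @export
cumulativeVariance <- function(basis, k) {
  stopifnot(is(basis, "PCABasis"), k >= 1L)
  lambda <- basis@eigenvalues
  if (k > length(lambda)) stop("k exceeds the number of components")
  tot <- sum(lambda)
  if (tot <= 0) stop("all-zero spectrum: cumulative variance undefined")
  sum(lambda[seq_len(k)]) / tot
}

#' Serialise a PCA basis to a plain-text file
#'
#' Writes mean, eigenvalues, eigenvectors, fit-atom indices and reference
#' coordinates in a line-oriented text format so separate sampling and
#' stitching runs share one basis.
#'
#' @param basis a [PCABasis-class].
#' @param path output path.
#' @param n_components number of leading components to keep (default all).
#' @return `path`, invisibly.
#' @export
writeBasis <- function(basis, path, n_components = NULL) {
  stopifnot(is(basis, "PCABasis"))
  k <- if (is.null(n_components)) length(basis@eigenvalues)
       else min(n_components, length(basis@eigenvalues))
  ref <- basis@fit_reference
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  writeLines(c(
    "# felstitch PCA basis, format 1",
    paste("centered", basis@centered),
    paste("n_coords", length(basis@mean_coords)),
    paste("n_components", k),
    paste("fit_indices", paste(ref@fit_indices, collapse = " ")),
    paste("mean", fmt(basis@mean_coords)),
    paste("eigenvalues", fmt(basis@eigenvalues[seq_len(k)])),
    vapply(seq_len(k), function(j)
      paste("eigenvector", fmt(basis@eigenvectors[, j])), character(1)),
    vapply(seq_len(nrow(ref@ref_coords)), function(i)
      paste("ref_coord", fmt(ref@ref_coords[i, ])), character(1))
  ), con)
  invisible(path)
}

#' Read a PCA basis written by [writeBasis()]
#'
#' @param path file path.
#' @return a [PCABasis-class].
#' @export
readBasis <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  key <- sub(" .*", "", lines)
  val <- sub("^[a-z_]+ ", "", lines)
  num <- function(s) as.numeric(strsplit(s, " +")[[1]])
  get1 <- function(k) val[match(k, key)]
  nc <- as.integer(get1("n_coords"))
  k <- as.integer(get1("n_components"))
  vecs <- vapply(val[key == "eigenvector"], num, numeric(nc))
  dimnames(vecs) <- NULL
  refc <- t(vapply(val[key == "ref_coord"], num, numeric(3)))
  dimnames(refc) <- NULL
  fit_idx <- as.integer(num(get1("fit_indices")))
  ref <- new("FitReference", ref_coords = refc, fit_indices = fit_idx,
             centroid = colMeans(refc))
  new("PCABasis", mean_coords = num(get1("mean")), eigenvectors = vecs,
      eigenvalues = num(get1("eigenvalues")), fit_reference = ref,
      centered = as.logical(get1("centered")))
}

#' Export eigenvectors as per-atom displacement arrows
#'
#' Writes a delimited table (one row per atom) with the atom position taken
#' from the ensemble-mean structure and the displacement of each requested
#' eigenvector scaled by `scale * sqrt(lambda_n)` — the data behind a
#' porcupine plot.
#'
#' @param basis a [PCABasis-class].
#' @param path output CSV path.
#' @param components components to export (default `1:2`).
#' @param scale multiplier on `sqrt(lambda_n)` (default 1).
#' @return the table, invisibly.
#' @export
writePorcupine <- function(basis, path, components = 1:2, scale = 1) {
  stopifnot(is(basis, "PCABasis"))
  n_atoms <- length(basis@mean_coords) / 3L
  pos <- matrix(basis@mean_coords, ncol = 3, byrow = TRUE)
  out <- data.frame(atom = seq_len(n_atoms), x = pos[, 1], y = pos[, 2],
                    z = pos[, 3])
  for (m in components) {
    d <- matrix(basis@eigenvectors[, m], ncol = 3, byrow = TRUE) *
      scale * sqrt(basis@eigenvalues[m])
    out[[paste0("dx", m)]] <- d[, 1]
    out[[paste0("dy", m)]] <- d[, 2]
    out[[paste0("dz", m)]] <- d[, 3]
  }
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
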