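#' Best-fit RMSD between two structures
#'
#' Superposes the selected atoms of `coords_a` onto those of `coords_b`
#' (optimal proper rotation after centroid removal) and returns the
#' root-mean-square deviation over that selection.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices.
#' @param indices atom indices to superpose and measure (default: all
#'   atoms; both structures use the same indices).
#' @return RMSD in Angstrom.
#' @export
pairwiseRmsd <- function(coords_a, coords_b, indices = NULL) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (is.null(indices)) indices <- seq_len(nrow(a))
  if (length(indices) < 3L) stop("need at least 3 atoms for superposition")
  if (max(indices) > nrow(a) || max(indices) > nrow(b))
    stop("selection indices out of range for one of the structures")
  asel <- a[indices, , drop = FALSE]
  bsel <- b[indices, , drop = FALSE]
  ref <- fitReference(bsel, seq_len(nrow(bsel)))
  fitted <- fitModel(asel, ref)$fitted
  target <- sweep(bsel, 2, ref@centroid)
  sqrt(mean(rowSums((fitted - target)^2)))
}

#' RMSD-centroid (representative) structure of an ensemble
#'
#' For each model i, Delta_i is the sum of its best-fit RMSDs to every
#' other model; the representative structure is the model with the
#' smallest Delta_i (lowest index on ties).
#'
#' @param ens a [ConformationEnsemble-class].
#' @param indices atom selection for the RMSD (default: Calpha atoms if
#'   present, else all atoms).
#' @return model index, with attribute `delta` holding all Delta_i.
#' @export
representativeStructure <- function(ens, indices = NULL) {
  stopifnot(is(ens, "ConformationEnsemble"))
  if (nModels(ens) == 0L) stop("empty ensemble")
  if (is.null(indices)) {
    ca <- which(ens@atoms$atom_name == "CA")
    indices <- if (length(ca) >= 3L) ca else seq_len(nAtoms(ens))
  }
  M <- nModels(ens)
  if (M == 1L) {
    out <- 1L; attr(out, "delta") <- 0
    return(out)
  }
  D <- matrix(0, M, M)
  for (i in seq_len(M - 1L)) {
    for (j in seq(i + 1L, M)) {
      D[i, j] <- D[j, i] <- pairwiseRmsd(ens@models[[i]], ens@models[[j]],
                                         indices)
    }
  }
  delta <- rowSums(D)
  out <- which.min(delta)              # lowest index wins ties
  attr(out, "delta") <- delta
  out
}

#' Closest ensemble member to a target structure
#'
#' @param ens a [ConformationEnsemble-class].
#' @param target_coords coordinate matrix of the target structure.
#' @param indices atom selection in the ensemble models.
#' @param target_indices matching selection in the target (default
#'   `indices`); must have the same length.
#' @return list with `model` (index) and `rmsd` (Angstrom).
#' @export
minRmsdToTarget <- function(ens, target_coords, indices = NULL,
                            target_indices = indices) {
  stopifnot(is(ens, "ConformationEnsemble"))
  if (nModels(ens) == 0L) stop("empty ensemble")
  target_coords <- as.matrix(target_coords)
  if (is.null(indices)) indices <- seq_len(nAtoms(ens))
  if (is.null(target_indices)) target_indices <- seq_len(nrow(target_coords))
  if (length(indices) != length(target_indices))
    stop("ensemble and target selections must have equal length")
  if (max(target_indices) > nrow(target_coords))
    stop("target selection out of range")
  tsel <- target_coords[target_indices, , drop = FALSE]
  ref <- fitReference(tsel, seq_len(nrow(tsel)))
  tctr <- sweep(tsel, 2, ref@centroid)
  r <- vapply(ens@models, function(m) {
    fitted <- fitModel(m[indices, , drop = FALSE], ref)$fitted
    sqrt(mean(rowSums((fitted - tctr)^2)))
  }, numeric(1))
  list(model = which.min(r), rmsd = min(r))
}

#' Residue contact pairs of one model
#'
#' Residues i and j (with |i - j| >= `min_seq_sep`) are in contact when any
#' atom of i lies strictly within `cutoff` of any atom of j.
#'
#' @param ens a [ConformationEnsemble-class].
#' @param model model index (default 1).
#' @param cutoff distance threshold in Angstrom (default 4.5).
#' @param min_seq_sep minimum residue-index separation (default 1,
#'   excluding only self-contacts).
#' @param heavy_only ignore hydrogen atoms (default FALSE: any atom
#'   present in the file counts).
#' @return two-column matrix of residue index pairs (i < j).
#' @export
residueContactPairs <- function(ens, model = 1L, cutoff = 4.5,
                                min_seq_sep = 1L, heavy_only = FALSE) {
  stopifnot(is(ens, "ConformationEnsemble"))
  at <- ens@atoms
  coords <- modelCoords(ens, model)
  keep <- rep(TRUE, nrow(at))
  if (heavy_only)
    keep <- !(toupper(at$element) == "H" |
                (!nzchar(at$element) & grepl("^H", at$atom_name)))
  coords <- coords[keep, , drop = FALSE]
  res <- at$residue_index[keep]
  d2 <- as.matrix(stats::dist(coords))^2
  close <- d2 < cutoff^2
  sep_ok <- abs(outer(res, res, "-")) >= min_seq_sep
  hit <- close & sep_ok
  if (!any(hit)) return(matrix(integer(0), 0, 2))
  idx <- which(hit, arr.ind = TRUE)
  pairs <- cbind(pmin(res[idx[, 1]], res[idx[, 2]]),
                 pmax(res[idx[, 1]], res[idx[, 2]]))
  pairs <- unique(pairs)
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

#' Contact probability of a residue pair across an ensemble
#'
#' @inheritParams residueContactPairs
#' @param pair length-2 residue index pair.
#' @return fraction of models in which the pair is in contact.
#' @export
contactProbability <- function(ens, pair, cutoff = 4.5, min_seq_sep = 1L,
                               heavy_only = FALSE) {
  stopifnot(is(ens, "ConformationEnsemble"), length(pair) == 2L)
  pair <- sort(as.integer(pair))
  hits <- vapply(seq_len(nModels(ens)), function(m) {
    cp <- residueContactPairs(ens, m, cutoff, min_seq_sep, heavy_only)
    any(cp[, 1] == pair[1] & cp[, 2] == pair[2])
  }, logical(1))
  mean(hits)
}

#' Contact probabilities for all observed residue pairs
#'
#' @inheritParams residueContactPairs
#' @return data.frame `i, j, probability` for every pair in contact in at
#'   least one model.
#' @export
contactProbabilityTable <- function(ens, cutoff = 4.5, min_seq_sep = 1L,
                                    heavy_only = FALSE) {
  stopifnot(is(ens, "ConformationEnsemble"))
  tallies <- list()
  for (m in seq_len(nModels(ens))) {
    cp <- residueContactPairs(ens, m, cutoff, min_seq_sep, heavy_only)
    if (nrow(cp)) {
      key <- paste(cp[, 1], cp[, 2])
      for (k in seq_along(key))
        tallies[[key[k]]] <- (tallies[[key[k]]] %||% 0L) + 1L
    }
  }
  if (!length(tallies))
    return(data.frame(i = integer(0), j = integer(0),
                      probability = numeric(0)))
  ij <- do.call(rbind, lapply(strsplit(names(tallies), " "), as.integer))
  out <- data.frame(i = ij[, 1], j = ij[, 2],
                    probability = unlist(tallies) / nModels(ens))
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mark contact-group formation on the collective-variable plane
#'
#' For every model: its (v1, v2) projection plus one logical per contact
#' group.  With `mode = "any"` (default) a group is formed when any of its
#' pairs is in contact; `mode = "all"` requires every pair.
#'
#' @inheritParams residueContactPairs
#' @param groups list of [ContactGroup-class] objects.
#' @param basis a [PCABasis-class] for the projections.
#' @param mode `"any"` or `"all"`.
#' @return data.frame `model, v1, v2` plus one logical column per group
#'   label.
#' @export
markContactGroups <- function(ens, groups, basis, cutoff = 4.5,
                              min_seq_sep = 1L, heavy_only = FALSE,
                              mode = c("any", "all")) {
  mode <- match.arg(mode)
  stopifnot(is(ens, "ConformationEnsemble"), is(basis, "PCABasis"))
  cv <- projectEnsemble(ens, basis, 1:2)
  out <- data.frame(model = seq_len(nModels(ens)), v1 = cv[, 1],
                    v2 = cv[, 2])
  flags <- matrix(FALSE, nModels(ens), length(groups))
  for (m in seq_len(nModels(ens))) {
    cp <- residueContactPairs(ens, m, cutoff, min_seq_sep, heavy_only)
    key <- if (nrow(cp)) paste(cp[, 1], cp[, 2]) else character(0)
    for (g in seq_along(groups)) {
      p <- groups[[g]]@pairs
      gkey <- paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
      flags[m, g] <- if (mode == "any") any(gkey %in% key)
                     else all(gkey %in% key)
    }
  }
  for (g in seq_along(groups)) out[[groups[[g]]@label]] <- flags[, g]
  out
}
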