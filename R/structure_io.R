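#' Read a multi-model PDB file into a ConformationEnsemble
#'
#' One model is taken per MODEL/ENDMDL block; a file without MODEL records
#' (a typical X-ray structure) yields a single-model ensemble.  All models
#' must contain the same atoms in the same order.  Alternate locations are
#' resolved by keeping the first altloc; by default the first chain
#' encountered is kept.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier to keep; `NULL` (default) keeps the first
#'   chain in the file.
#' @param include_hetatm keep HETATM records of the selected chain (ions,
#'   ligands, waters).  Default `FALSE`.
#' @return a [ConformationEnsemble-class].
#' @export
readPdbEnsemble <- function(path, chain = NULL, include_hetatm = FALSE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  .checkModelAtomCounts(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if (!include_hetatm) keep <- keep & at$type == "ATOM"
  if (!any(keep)) stop("no atoms left after HETATM filtering in ", path)
  sel_chain <- if (is.null(chain)) at$chain[which(keep)[1]] else chain
  keep <- keep & (at$chain %in% sel_chain | is.na(at$chain))
  # first altloc wins: keep blank altlocs plus, per atom identity, the
  # first non-blank altloc code seen in the file
  alt <- at$alt
  alt[is.na(alt)] <- ""
  first_alt <- unique(alt[keep & nzchar(alt)])[1]
  if (!is.na(first_alt)) keep <- keep & (!nzchar(alt) | alt == first_alt)
  if (!any(keep)) stop("empty atom selection for chain ", sel_chain)

  idx <- which(keep)
  atoms <- data.frame(
    residue_index = as.integer(at$resno[idx]),
    residue_name = at$resid[idx],
    atom_name = at$elety[idx],
    element = ifelse(is.na(at$elesy[idx]), "", at$elesy[idx]),
    chain_id = ifelse(is.na(at$chain[idx]), "", at$chain[idx]),
    stringsAsFactors = FALSE)

  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  models <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, cols], ncol = 3, byrow = TRUE))
  conformationEnsemble(models, atoms, label = basename(path))
}

# Pre-scan the raw file so an atom-count mismatch can name the offending
# model (bio3d's own error does not).
.checkModelAtomCounts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) < 2L) return(invisible(NULL))
  ends <- which(rec == "ENDMDL")
  if (length(ends) < length(model_starts))
    stop("PDB file has MODEL records without matching ENDMDL: ", path)
  counts <- vapply(seq_along(model_starts), function(i) {
    block <- rec[model_starts[i]:ends[i]]
    sum(block %in% c("ATOM  ", "HETATM"))
  }, integer(1))
  bad <- which(counts != counts[1])
  if (length(bad))
    stop(sprintf(
      "model %d has %d atom records but model 1 has %d (file %s)",
      bad[1], counts[bad[1]], counts[1], basename(path)))
  invisible(NULL)
}

#' Select atoms by name and residue range
#'
#' @param ens a [ConformationEnsemble-class].
#' @param atom_name atom name to keep (e.g. `"CA"`); `NULL` keeps all names.
#' @param residue_range inclusive 1-based `c(first, last)` residue numbers;
#'   `NULL` keeps all residues.
#' @return integer atom indices, ordered as in the atom table (by residue).
#' @export
selectAtoms <- function(ens, atom_name = "CA", residue_range = NULL) {
  stopifnot(is(ens, "ConformationEnsemble"))
  at <- ens@atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(atom_name)) keep <- keep & at$atom_name %in% atom_name
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    if (residue_range[1] < min(at$residue_index) ||
        residue_range[2] > max(at$residue_index))
      stop(sprintf("residue range %d-%d outside ensemble residues %d-%d",
                   residue_range[1], residue_range[2],
                   min(at$residue_index), max(at$residue_index)))
    keep <- keep & at$residue_index >= residue_range[1] &
      at$residue_index <= residue_range[2]
  }
  idx <- which(keep)
  if (!length(idx)) stop("empty atom selection (fitting would be undefined)")
  idx[order(at$residue_index[idx], idx)]
}

#' Write a ConformationEnsemble as a (multi-model) PDB file
#'
#' Multi-model ensembles are written with MODEL/ENDMDL records; a
#' single-model ensemble is written as a plain coordinate file.  Coordinates
#' survive a round trip through [readPdbEnsemble()] to PDB fixed-point
#' precision (0.001 Angstrom).
#'
#' @param ens a [ConformationEnsemble-class].
#' @param path output file path.
#' @param remarks optional character vector written as REMARK lines.
#' @return `path`, invisibly.
#' @export
writePdbModels <- function(ens, path, remarks = NULL) {
  stopifnot(is(ens, "ConformationEnsemble"))
  if (nModels(ens) == 0L) stop("cannot write an empty ensemble")
  at <- ens@atoms
  xyz <- do.call(rbind, lapply(ens@models, function(m) as.vector(t(m))))
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path, xyz = xyz,
      type = rep("ATOM", nrow(at)),
      resno = at$residue_index, resid = at$residue_name,
      eleno = seq_len(nrow(at)), elety = at$atom_name,
      chain = ifelse(nzchar(at$chain_id), at$chain_id, "A"),
      elesy = at$element)
    TRUE
  }, error = function(e) stop("cannot write PDB file ", path, ": ",
                              conditionMessage(e)))
  if (!is.null(remarks) || nzchar(ens@label)) {
    hdr <- sprintf("REMARK   6 %s", c(
      sprintf("ensemble '%s', %d models, written by felstitch",
              ens@label, nModels(ens)), remarks))
    body <- readLines(path, warn = FALSE)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Restrict an ensemble to an atom subset
#'
#' @param ens a [ConformationEnsemble-class].
#' @param indices atom indices to keep (e.g. from [selectAtoms()]).
#' @return a [ConformationEnsemble-class] over the selected atoms.
#' @export
subsetEnsemble <- function(ens, indices) {
  stopifnot(is(ens, "ConformationEnsemble"))
  indices <- as.integer(indices)
  if (!length(indices)) stop("empty atom selection")
  if (max(indices) > nAtoms(ens)) stop("selection indices out of range")
  conformationEnsemble(
    lapply(ens@models, function(m) m[indices, , drop = FALSE]),
    ens@atoms[indices, , drop = FALSE], label = ens@label)
}
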