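#' Assemble the stitched free-energy landscape
#'
#' Every retained sample of region i enters its (v1, v2) bin with weight
#' exp(W_i) / M(v), where M is the number of sampling regions covering the
#' point; the weighted histogram is normalised by the total weighted count
#' and Boltzmann-inverted, F = -kT ln(density), min-shifted so the lowest
#' populated bin is 0.  Adding a constant to every W leaves the result
#' unchanged (weights are a gauge).
#'
#' @param samples_list list of per-region retained samples (results of
#'   [clipToRegion()]).
#' @param weights a [WeightTable-class] covering every populated region.
#' @param grid the [RegionGrid-class] the samples were clipped against
#'   (used for the multiplicity correction).
#' @param v1_edges,v2_edges bin boundaries; see [chooseBinEdges()] for an
#'   automatic choice.
#' @param temperature_K temperature (default 300 K).
#' @return a [FELGrid-class]; bins without samples are masked.
#' @export
assembleFel <- function(samples_list, weights, grid, v1_edges, v2_edges,
                        temperature_K = 300) {
  stopifnot(is(weights, "WeightTable"), is(grid, "RegionGrid"))
  W <- weights@W
  cv <- NULL; wt <- NULL
  for (s in samples_list) {
    if (s$L == 0L) next
    if (is.na(W[s$region_id]))
      stop(sprintf("region %d has samples but no weight", s$region_id))
    M <- multiplicity(s$cv, grid)
    if (any(M == 0L))
      stop("retained samples must lie inside their sampling region")
    cv <- rbind(cv, s$cv)
    wt <- c(wt, exp(W[s$region_id]) / M)
  }
  if (is.null(cv)) stop("no samples to assemble")
  binFel(cv, v1_edges, v2_edges, kT = thermalEnergy(temperature_K),
         weights = wt)
}

#' Bin edges adapted to the sample density
#'
#' Starts from `max_bins` bins per axis over the data range and coarsens
#' (by steps of about sqrt(2)) until the median count of occupied bins
#' reaches `target_median`, so Boltzmann inversion is not dominated by
#' single-sample bins.
#'
#' @param cv two-column matrix of all (v1, v2) samples.
#' @param target_median desired median occupied-bin count (default 20).
#' @param max_bins,min_bins per-axis bin-count bounds.
#' @return list with `v1` and `v2` bin-edge vectors.
#' @export
chooseBinEdges <- function(cv, target_median = 20, max_bins = c(40L, 32L),
                           min_bins = c(10L, 8L)) {
  cv <- as.matrix(cv)
  r1 <- range(cv[, 1]); r2 <- range(cv[, 2])
  n1 <- max_bins[1]; n2 <- max_bins[2]
  repeat {
    e1 <- seq(r1[1], r1[2], length.out = n1 + 1L)
    e2 <- seq(r2[1], r2[2], length.out = n2 + 1L)
    i1 <- findInterval(cv[, 1], e1, rightmost.closed = TRUE)
    i2 <- findInterval(cv[, 2], e2, rightmost.closed = TRUE)
    counts <- table((i1 - 1L) * n2 + i2)
    if (stats::median(counts) >= target_median ||
        (n1 <= min_bins[1] && n2 <= min_bins[2]))
      return(list(v1 = e1, v2 = e2))
    n1 <- max(min_bins[1], round(n1 / sqrt(2)))
    n2 <- max(min_bins[2], round(n2 / sqrt(2)))
  }
}

#' One-dimensional landscape by rectangle averaging
#'
#' For each bin along the kept axis, the arithmetic mean of the unmasked
#' free-energy values across the transverse extent of the rectangle.
#'
#' @param fel a [FELGrid-class].
#' @param rectangle length-4 `c(v1_min, v1_max, v2_min, v2_max)`.
#' @param axis `"v1"` or `"v2"`: the axis the profile runs along.
#' @return data.frame with `center`, `F` (NA where every transverse bin is
#'   masked) and `n_bins` (transverse bins averaged).
#' @export
marginalFel <- function(fel, rectangle, axis = c("v1", "v2")) {
  axis <- match.arg(axis)
  stopifnot(is(fel, "FELGrid"), length(rectangle) == 4L)
  ctr <- felBinCenters(fel)
  in1 <- ctr$v1 >= rectangle[1] & ctr$v1 <= rectangle[2]
  in2 <- ctr$v2 >= rectangle[3] & ctr$v2 <= rectangle[4]
  if (!any(in1) || !any(in2))
    stop("rectangle does not intersect the landscape grid")
  sub <- fel@F[in1, in2, drop = FALSE]
  if (axis == "v1") {
    F <- apply(sub, 1, function(x) mean(x, na.rm = TRUE))
    n <- apply(sub, 1, function(x) sum(!is.na(x)))
    center <- ctr$v1[in1]
  } else {
    F <- apply(sub, 2, function(x) mean(x, na.rm = TRUE))
    n <- apply(sub, 2, function(x) sum(!is.na(x)))
    center <- ctr$v2[in2]
  }
  F[n == 0L] <- NA_real_
  data.frame(center = center, F = F, n_bins = n)
}

#' Basin-to-saddle barrier heights between two landscape regions
#'
#' F_a and F_b are the minimum free energies inside the two rectangles;
#' the saddle is the minimax over 4-connected paths of unmasked bins
#' (the lowest value F* such that the two minima connect through bins with
#' F <= F*).  Returns both barrier heights `F_saddle - F_a` and
#' `F_saddle - F_b`; both are >= 0 and invariant under a constant shift
#' of F.
#'
#' @param fel a [FELGrid-class].
#' @param region_a,region_b length-4 rectangles in CV coordinates.
#' @return named numeric `c(ddF_a, ddF_b)`, with attributes `F_saddle`,
#'   `F_a`, `F_b`.
#' @export
barrierDeltaDeltaF <- function(fel, region_a, region_b) {
  stopifnot(is(fel, "FELGrid"))
  ctr <- felBinCenters(fel)
  binset <- function(rect) {
    ok <- outer(ctr$v1 >= rect[1] & ctr$v1 <= rect[2],
                ctr$v2 >= rect[3] & ctr$v2 <= rect[4], "&") & !fel@mask
    which(ok)
  }
  a_bins <- binset(region_a); b_bins <- binset(region_b)
  if (!length(a_bins) || !length(b_bins))
    stop("both rectangles must contain unmasked bins")
  Fa <- min(fel@F[a_bins]); Fb <- min(fel@F[b_bins])
  amin <- a_bins[which.min(fel@F[a_bins])]
  bmin <- b_bins[which.min(fel@F[b_bins])]

  # flood in order of increasing F; the saddle is the F at which the two
  # minima first join one connected component (union-find)
  n1 <- nrow(fel@F); n2 <- ncol(fel@F)
  open <- which(!fel@mask)
  ord <- open[order(fel@F[open])]
  parent <- seq_len(n1 * n2)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  active <- logical(n1 * n2)
  for (cell in ord) {
    active[cell] <- TRUE
    i <- (cell - 1L) %% n1 + 1L; j <- (cell - 1L) %/% n1 + 1L
    for (nb in c(if (i > 1L) cell - 1L, if (i < n1) cell + 1L,
                 if (j > 1L) cell - n1, if (j < n2) cell + n1)) {
      if (active[nb]) {
        ra <- find(cell); rb <- find(nb)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (active[amin] && active[bmin] && find(amin) == find(bmin)) {
      Fs <- fel@F[cell]
      out <- c(ddF_a = Fs - Fa, ddF_b = Fs - Fb)
      attr(out, "F_saddle") <- Fs
      attr(out, "F_a") <- Fa; attr(out, "F_b") <- Fb
      return(out)
    }
  }
  stop("no unmasked path connects the two regions")
}

#' Gauge-fixed difference between two landscapes on shared bins
#'
#' Free energies are defined up to an additive constant, so the comparison
#' subtracts the mean offset over the bins that are unmasked (and
#' sufficiently populated) in both grids before measuring the discrepancy.
#'
#' @param fel_a,fel_b two [FELGrid-class] objects on identical bin edges.
#' @param min_count only compare bins whose effective count reaches this in
#'   both grids (default 0: all mutually unmasked bins).
#' @return list with `mean_abs` (mean |Delta F| in kcal/mol), `max_abs`,
#'   `n_bins` compared and the removed `offset`.
#' @export
compareFel <- function(fel_a, fel_b, min_count = 0) {
  stopifnot(is(fel_a, "FELGrid"), is(fel_b, "FELGrid"))
  if (!isTRUE(all.equal(fel_a@v1_edges, fel_b@v1_edges)) ||
      !isTRUE(all.equal(fel_a@v2_edges, fel_b@v2_edges)))
    stop("landscapes must share bin edges")
  both <- !fel_a@mask & !fel_b@mask &
    fel_a@counts >= min_count & fel_b@counts >= min_count
  if (!any(both)) stop("no mutually well-sampled bins")
  d <- fel_a@F[both] - fel_b@F[both]
  off <- mean(d)
  list(mean_abs = mean(abs(d - off)), max_abs = max(abs(d - off)),
       n_bins = sum(both), offset = off)
}

#' Export a landscape as a delimited grid file
#'
#' One row per bin: v1_center, v2_center, F (empty on masked bins), mask,
#' count.
#'
#' @param fel a [FELGrid-class].
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
writeFelGrid <- function(fel, path) {
  stopifnot(is(fel, "FELGrid"))
  ctr <- felBinCenters(fel)
  out <- data.frame(
    v1_center = rep(ctr$v1, times = length(ctr$v2)),
    v2_center = rep(ctr$v2, each = length(ctr$v1)),
    F = as.vector(fel@F), mask = as.vector(fel@mask),
    count = as.vector(fel@counts))
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write (label, v1, v2) overlay rows for external structures
#'
#' Companion file for plotting reference structures (e.g. projected NMR or
#' X-ray models) on top of a landscape.
#'
#' @param labels character vector.
#' @param cv two-column matrix of projections.
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
writeCvOverlay <- function(labels, cv, path) {
  cv <- as.matrix(cv)
  out <- data.frame(label = labels, v1 = cv[, 1], v2 = cv[, 2])
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
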