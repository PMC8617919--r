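#' Partition the collective-variable plane into overlapping regions
#'
#' The domain rectangle is tiled by `n_rows` x `n_cols` disjoint small
#' areas (columns run along v1, rows along v2; region ids are row-major,
#' v1-fastest).  Each sampling region is its small area grown by `margin`
#' on every edge interior to the domain, so horizontally or vertically
#' adjacent sampling regions overlap by `2 * margin` along the shared axis
#' and diagonal neighbours share a corner square.
#'
#' @param domain length-4 numeric `c(v1_min, v1_max, v2_min, v2_max)`.
#' @param n_rows,n_cols number of small areas along v2 and v1.
#' @param margin overlap margin (Angstrom); must be less than half the
#'   small-area width on both axes.
#' @return a [RegionGrid-class].
#' @export
partitionPlane <- function(domain, n_rows, n_cols, margin) {
  stopifnot(length(domain) == 4L, n_rows >= 1L, n_cols >= 1L, margin >= 0)
  w1 <- (domain[2] - domain[1]) / n_cols
  w2 <- (domain[4] - domain[3]) / n_rows
  if (w1 <= 0 || w2 <= 0) stop("degenerate domain rectangle")
  if (margin >= w1 / 2 || margin >= w2 / 2)
    stop(sprintf(
      "margin %g must be smaller than half the small-area width (%g x %g)",
      margin, w1, w2))
  sa <- matrix(NA_real_, n_rows * n_cols, 4)
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      id <- (r - 1L) * n_cols + c
      sa[id, ] <- c(domain[1] + (c - 1) * w1, domain[1] + c * w1,
                    domain[3] + (r - 1) * w2, domain[3] + r * w2)
    }
  }
  regionGridFromRectangles(sa, margin, domain)
}

#' Build a RegionGrid from an explicit small-area list
#'
#' Accepts irregular layouts (the small areas need not fill a full
#' rectangle).  Each sampling region is its small area grown by `margin`
#' on every edge interior to the domain; adjacency pairs are regions whose
#' sampling rectangles intersect (including shared edges and corners).
#'
#' @param small_areas n x 4 matrix, columns v1_min, v1_max, v2_min, v2_max.
#' @param margin overlap margin (Angstrom).
#' @param domain overall rectangle; default the bounding box of the areas.
#' @return a [RegionGrid-class].
#' @export
regionGridFromRectangles <- function(small_areas, margin, domain = NULL) {
  sa <- as.matrix(small_areas)
  dimnames(sa) <- NULL
  stopifnot(ncol(sa) == 4L, margin >= 0)
  if (is.null(domain))
    domain <- c(min(sa[, 1]), max(sa[, 2]), min(sa[, 3]), max(sa[, 4]))
  tol <- 1e-9 * max(1, abs(domain))
  grow <- function(lo, hi, dlo, dhi)
    c(if (lo - dlo > tol) -margin else 0, if (dhi - hi > tol) margin else 0)
  sr <- sa
  for (i in seq_len(nrow(sa))) {
    g1 <- grow(sa[i, 1], sa[i, 2], domain[1], domain[2])
    g2 <- grow(sa[i, 3], sa[i, 4], domain[3], domain[4])
    sr[i, ] <- sa[i, ] + c(g1, g2)
  }
  adj <- NULL
  for (i in seq_len(nrow(sr))) {
    for (j in seq_len(nrow(sr))) {
      if (j <= i) next
      if (.rectsTouch(sr[i, ], sr[j, ], tol)) adj <- rbind(adj, c(i, j))
    }
  }
  if (is.null(adj)) adj <- matrix(integer(0), 0, 2)
  new("RegionGrid", small_areas = sa, sampling_regions = sr,
      margin = margin, domain = as.numeric(domain), adjacency = adj)
}

.rectsTouch <- function(a, b, tol = 1e-9) {
  a[1] <= b[2] + tol && b[1] <= a[2] + tol &&
    a[3] <= b[4] + tol && b[3] <= a[4] + tol
}

.rectIntersection <- function(a, b) {
  c(max(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), min(a[4], b[4]))
}

.inRect <- function(cv, rect) {
  cv[, 1] >= rect[1] & cv[, 1] <= rect[2] &
    cv[, 2] >= rect[3] & cv[, 2] <= rect[4]
}

#' Apply the sampling-region exclusion rule
#'
#' Samples outside the region's sampling rectangle (where the restraint
#' energy is non-zero) are excluded from all landscape statistics.
#'
#' @param raw_cv two-column matrix of (v1, v2) samples from one region's
#'   run.
#' @param grid a [RegionGrid-class].
#' @param region_id which region the samples belong to.
#' @return list with `region_id`, `cv` (the retained rows) and `L` (the
#'   retained sample count).
#' @export
clipToRegion <- function(raw_cv, grid, region_id) {
  stopifnot(is(grid, "RegionGrid"))
  raw_cv <- as.matrix(raw_cv)
  rect <- grid@sampling_regions[region_id, ]
  keep <- .inRect(raw_cv, rect)
  list(region_id = as.integer(region_id),
       cv = raw_cv[keep, , drop = FALSE], L = sum(keep))
}

#' Count samples in the overlap of two adjacent sampling regions
#'
#' @param samples_i,samples_j retained samples (from [clipToRegion()]) of
#'   two adjacent regions.
#' @param grid a [RegionGrid-class].
#' @return `c(N_i, N_j)`: each region's sample count inside the geometric
#'   intersection of the two sampling rectangles.
#' @export
countOverlap <- function(samples_i, samples_j, grid) {
  stopifnot(is(grid, "RegionGrid"))
  i <- samples_i$region_id; j <- samples_j$region_id
  adj <- grid@adjacency
  if (!any((adj[, 1] == min(i, j)) & (adj[, 2] == max(i, j))))
    stop(sprintf("regions %d and %d are not adjacent", i, j))
  strip <- .rectIntersection(grid@sampling_regions[i, ],
                             grid@sampling_regions[j, ])
  if (strip[1] > strip[2] || strip[3] > strip[4]) return(c(0L, 0L))
  c(sum(.inRect(samples_i$cv, strip)), sum(.inRect(samples_j$cv, strip)))
}

#' Relative log-weight between two overlapping regions
#'
#' Both regions sample the same equilibrium density inside their overlap,
#' so the weighted counts must match there: exp(W_i) N_i = exp(W_j) N_j,
#' giving W_j - W_i = ln(N_i / N_j) (the default `"density"` convention).
#' `"counts"` applies the opposite sign, log N_j - log N_i, as a documented
#' alternative.
#'
#' @param N_i,N_j overlap sample counts from [countOverlap()].
#' @param convention `"density"` (default) or `"counts"`.
#' @return omega_ij such that W_j = W_i + omega_ij, or `NA` (unusable edge)
#'   when either count is zero.
#' @export
relativeWeight <- function(N_i, N_j, convention = c("density", "counts")) {
  convention <- match.arg(convention)
  if (N_i <= 0 || N_j <= 0) return(NA_real_)
  if (convention == "density") log(N_i) - log(N_j) else log(N_j) - log(N_i)
}

#' Overlap counts for every adjacent region pair
#'
#' @param samples_list list of per-region samples ([clipToRegion()]
#'   results); regions that were not simulated may be absent.
#' @param grid a [RegionGrid-class].
#' @return list with `edges` (data.frame `i, j, N_i, N_j` over adjacent
#'   pairs where both regions have samples) and `L` (retained sample count
#'   per region, 0 where absent).
#' @export
computeOverlapCounts <- function(samples_list, grid) {
  stopifnot(is(grid, "RegionGrid"))
  n <- nRegions(grid)
  L <- integer(n)
  byid <- vector("list", n)
  for (s in samples_list) {
    byid[[s$region_id]] <- s
    L[s$region_id] <- s$L
  }
  adj <- grid@adjacency
  rows <- lapply(seq_len(nrow(adj)), function(e) {
    i <- adj[e, 1]; j <- adj[e, 2]
    if (L[i] == 0L || L[j] == 0L) return(NULL)
    nn <- countOverlap(byid[[i]], byid[[j]], grid)
    data.frame(i = i, j = j, N_i = nn[1], N_j = nn[2])
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges))
    edges <- data.frame(i = integer(0), j = integer(0),
                        N_i = integer(0), N_j = integer(0))
  list(edges = edges, L = L)
}

#' Choose the seed region for weight propagation
#'
#' The region with the largest number of usable overlap edges (positive
#' counts on both sides); ties go to the lowest region index.
#'
#' @param grid a [RegionGrid-class].
#' @param overlap_counts result of [computeOverlapCounts()].
#' @return region index.
#' @export
chooseSeedRegion <- function(grid, overlap_counts) {
  L <- overlap_counts$L
  if (!any(L > 0)) stop("no populated regions")
  e <- overlap_counts$edges
  usable <- e[e$N_i > 0 & e$N_j > 0, , drop = FALSE]
  deg <- tabulate(c(usable$i, usable$j), nbins = nRegions(grid))
  deg[L == 0] <- -1L
  which.max(deg)                        # which.max takes the lowest tie
}

#' Propagate region weights over the overlap graph
#'
#' Starting from W(seed) = 0, breadth-first propagation of
#' W_j = W_i + omega_ij over usable edges (positive overlap counts on both
#' sides, edge and diagonal neighbours alike) assigns every populated
#' region exactly once.  `method = "leastsq"` instead solves all usable
#' edges simultaneously in the least-squares sense (exact when the
#' edge log-ratios are cycle-consistent, and averaging the noise when not).
#'
#' @param grid a [RegionGrid-class].
#' @param overlap_counts result of [computeOverlapCounts()].
#' @param seed_region starting region; default [chooseSeedRegion()].
#' @param convention sign convention passed to [relativeWeight()].
#' @param method `"bfs"` (default) or `"leastsq"`.
#' @return a [WeightTable-class].  Unpopulated regions get `W = NA`; if the
#'   populated regions do not form one connected component an error lists
#'   the components.
#' @export
propagateWeights <- function(grid, overlap_counts, seed_region = NULL,
                             convention = c("density", "counts"),
                             method = c("bfs", "leastsq")) {
  convention <- match.arg(convention)
  method <- match.arg(method)
  stopifnot(is(grid, "RegionGrid"))
  n <- nRegions(grid)
  L <- overlap_counts$L
  e <- overlap_counts$edges
  usable <- e[e$N_i > 0 & e$N_j > 0, , drop = FALSE]
  if (is.null(seed_region))
    seed_region <- chooseSeedRegion(grid, overlap_counts)
  if (L[seed_region] == 0L) stop("seed region has no samples")

  W <- rep(NA_real_, n)
  linked <- rep(FALSE, n)
  W[seed_region] <- 0; linked[seed_region] <- TRUE
  # breadth-first spanning pass: each region assigned once
  queue <- seed_region
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    inc <- which(usable$i == a | usable$j == a)
    for (r in inc) {
      b <- if (usable$i[r] == a) usable$j[r] else usable$i[r]
      if (linked[b]) next
      Na <- if (usable$i[r] == a) usable$N_i[r] else usable$N_j[r]
      Nb <- if (usable$i[r] == a) usable$N_j[r] else usable$N_i[r]
      W[b] <- W[a] + relativeWeight(Na, Nb, convention)
      linked[b] <- TRUE
      queue <- c(queue, b)
    }
  }
  pop <- which(L > 0)
  if (!all(linked[pop])) {
    comps <- .componentLabels(pop, usable)
    stop("overlap graph is disconnected; components: ",
         paste(vapply(comps, function(cc) paste0("{", paste(cc, collapse = ","), "}"),
                      character(1)), collapse = " "))
  }
  if (method == "leastsq" && nrow(usable) > 0) {
    idx <- match(seq_len(n), pop)      # positions of regions among populated
    m <- length(pop)
    A <- matrix(0, nrow(usable), m)
    b <- numeric(nrow(usable))
    for (r in seq_len(nrow(usable))) {
      A[r, idx[usable$i[r]]] <- -1
      A[r, idx[usable$j[r]]] <- 1
      b[r] <- relativeWeight(usable$N_i[r], usable$N_j[r], convention)
    }
    fixed <- idx[seed_region]
    free <- setdiff(seq_len(m), fixed)
    sol <- qr.solve(A[, free, drop = FALSE], b)
    Wp <- numeric(m); Wp[free] <- sol
    W[pop] <- Wp - Wp[fixed]
  }
  deg <- tabulate(c(usable$i, usable$j), nbins = n)
  new("WeightTable", W = W, linked = linked,
      seed_region = as.integer(seed_region), n_edges_used = as.integer(deg))
}

.componentLabels <- function(nodes, usable) {
  comp <- setNames(seq_along(nodes), nodes)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (r in seq_len(nrow(usable))) {
    a <- match(usable$i[r], nodes); b <- match(usable$j[r], nodes)
    ra <- find(a); rb <- find(b)
    if (ra != rb) comp[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  unname(split(nodes, roots))
}

#' Multiplicity of a collective-variable point
#'
#' The number of sampling regions whose rectangle contains the point;
#' samples in k-fold covered zones are down-weighted by 1/k in the
#' assembled landscape to avoid double counting.
#'
#' @param v two-column matrix (or length-2 vector) of (v1, v2) points.
#' @param grid a [RegionGrid-class].
#' @return integer vector of region cover counts; 0 (with a warning) for
#'   points outside every sampling region.
#' @export
multiplicity <- function(v, grid) {
  stopifnot(is(grid, "RegionGrid"))
  v <- if (is.null(dim(v))) matrix(v, ncol = 2) else as.matrix(v)
  m <- integer(nrow(v))
  for (i in seq_len(nRegions(grid)))
    m <- m + as.integer(.inRect(v, grid@sampling_regions[i, ]))
  if (any(m == 0L))
    warning(sum(m == 0L), " point(s) outside every sampling region")
  m
}

#' Write / read a region layout as a delimited table
#'
#' Columns: region_id, v1_min, v1_max, v2_min, v2_max (small areas);
#' the margin is stored in the header comment.
#'
#' @param grid a [RegionGrid-class].
#' @param path file path.
#' @return `path` invisibly ([writeRegionLayout()]); a
#'   [RegionGrid-class] ([readRegionLayout()]).
#' @export
writeRegionLayout <- function(grid, path) {
  stopifnot(is(grid, "RegionGrid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# margin %.17g domain %.17g %.17g %.17g %.17g",
                     grid@margin, grid@domain[1], grid@domain[2],
                     grid@domain[3], grid@domain[4]), con)
  sa <- grid@small_areas
  df <- data.frame(region_id = seq_len(nrow(sa)), v1_min = sa[, 1],
                   v1_max = sa[, 2], v2_min = sa[, 3], v2_max = sa[, 4])
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegionLayout
#' @export
readRegionLayout <- function(path) {
  hdr <- readLines(path, n = 1L)
  vals <- as.numeric(strsplit(hdr, " +")[[1]][c(3, 5:8)])
  df <- read.csv(path, comment.char = "#")
  regionGridFromRectangles(as.matrix(df[, c("v1_min", "v1_max", "v2_min",
                                            "v2_max")]),
                           margin = vals[1], domain = vals[2:5])
}
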