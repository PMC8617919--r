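#' Default pipeline configuration
#'
#' Returns the configuration list driving the end-to-end toy demonstration.
#' All values can be overridden by a YAML file ([readRunConfig()]) or a
#' partial list merged over these defaults.
#'
#' @return nested named list; see the fields in the source for units.
#' @export
defaultRunConfig <- function() {
  list(
    toy = list(n_beads = 10L, bond_k = 5, bond_length = 3.8,
               barrier_h = 1.8, q0 = 16, w = 4, delta_u = 0,
               bend_k = 150, plane_k = 10, z_amplitude = 2, chiral_k = 2,
               temperature = 300),
    sampling = list(n_steps_reference = 400000L,
                    n_steps_region = 2000000L, n_runs_per_region = 4L,
                    burn_frac = 0.1, dt = 0.005, friction = 1,
                    save_every = 20L),
    restraint = list(spring_constant = 1.0),
    weights = list(method = "bfs", convention = "density"),
    regions = list(n_rows = 3L, n_cols = 3L, margin_frac = 0.2,
                   pad_frac = 0.02),
    fel = list(target_median = 20, max_bins = c(36L, 28L),
               min_bins = c(12L, 10L), min_compare_count = 100),
    oracle = list(n_steps = 12000000L),
    repeats = 3L)
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override [defaultRunConfig()]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  mergeConfig(defaultRunConfig(), user)
}

#' @rdname readRunConfig
#' @param base,override configuration lists; `override` wins recursively.
#' @export
mergeConfig <- function(base, override) {
  if (is.null(override)) return(base)
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      mergeConfig(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

# Stage 1: toy model, unbiased reference ensemble, PCA basis, region grid,
# and a start structure per region.
.pipelineSetup <- function(config, seed, verbose = FALSE) {
  tc <- config$toy
  built <- buildToyModel(n_beads = tc$n_beads, bond_k = tc$bond_k,
                         bond_length = tc$bond_length,
                         barrier_h = tc$barrier_h, q0 = tc$q0, w = tc$w,
                         delta_u = tc$delta_u, bend_k = tc$bend_k,
                         plane_k = tc$plane_k,
                         z_amplitude = tc$z_amplitude,
                         chiral_k = tc$chiral_k,
                         temperature = tc$temperature, seed = seed)
  sc <- config$sampling
  if (verbose) message("reference run (", sc$n_steps_reference, " steps)")
  ref_traj <- langevinRun(built$model, built$coords,
                          sc$n_steps_reference, dt = sc$dt,
                          friction = sc$friction, seed = seed + 1L,
                          save_every = sc$save_every)
  ens <- trajectoryToEnsemble(ref_traj, label = "toy reference")
  # superpose on all beads: distributing the fit over the whole chain
  # suppresses the lever-amplified frame wobble a single-lobe fit leaves
  # in the distal coordinates, so the collective variables track the
  # hinge coordinate tightly and every region mixes internally
  ref <- fitReference(modelCoords(ens, 1), seq_len(nAtoms(ens)))
  basis <- buildPcaBasis(ens, ref)
  cv_ref <- projectEnsemble(ens, basis, 1:2)

  rc <- config$regions
  pad <- rc$pad_frac * c(diff(range(cv_ref[, 1])), diff(range(cv_ref[, 2])))
  domain <- c(min(cv_ref[, 1]) - pad[1], max(cv_ref[, 1]) + pad[1],
              min(cv_ref[, 2]) - pad[2], max(cv_ref[, 2]) + pad[2])
  w1 <- (domain[2] - domain[1]) / rc$n_cols
  w2 <- (domain[4] - domain[3]) / rc$n_rows
  grid <- partitionPlane(domain, rc$n_rows, rc$n_cols,
                         margin = rc$margin_frac * min(w1, w2))

  # candidate start structures per region: reference frames actually
  # located inside the sampling rectangle (equilibrium draws), randomly
  # subsampled.  Each of the region's runs starts from a different
  # candidate, so the pooled samples stratify over slow coordinates the
  # CV pair does not resolve.  Regions never visited by the reference run
  # are not simulated (their bins are unreachable for the reference
  # comparison too).
  sr <- samplingRegions(grid)
  set.seed(seed + 50L)
  starts <- lapply(seq_len(nRegions(grid)), function(i) {
    inside <- which(cv_ref[, 1] >= sr[i, 1] & cv_ref[, 1] <= sr[i, 2] &
                      cv_ref[, 2] >= sr[i, 3] & cv_ref[, 2] <= sr[i, 4])
    if (!length(inside)) return(NULL)
    pick <- if (length(inside) > 24L) sample(inside, 24L) else
      inside[sample.int(length(inside))]
    lapply(pick, function(f) modelCoords(ens, f))
  })
  list(model = built$model, init_coords = built$coords, basis = basis,
       grid = grid, starts = starts, cv_ref = cv_ref)
}

#' Restrained sampling of every region
#'
#' For each sampling region, runs `n_runs_per_region` independent
#' restrained Langevin simulations (distinct seeds, distinct start
#' structures drawn from the reference ensemble inside the region), drops
#' the leading `burn_frac` of each run as equilibration, pools the
#' samples, and applies the exclusion rule.  Regions without a start
#' structure are skipped.
#'
#' @param model a [ToyBeadModel-class].
#' @param basis a [PCABasis-class].
#' @param grid a [RegionGrid-class].
#' @param starts per-region list of candidate start-coordinate matrices
#'   (`NULL` for regions that are not simulated); a single matrix is also
#'   accepted.
#' @param config configuration list (see [defaultRunConfig()]).
#' @param seed_base integer; run r of region i uses seed
#'   `seed_base + 31 * i + r`.
#' @param verbose print progress.
#' @return list with `raw` (per-region list of [Trajectory-class]) and
#'   `clipped` (per-region pooled [clipToRegion()] results).
#' @export
sampleRegions <- function(model, basis, grid, starts, config, seed_base,
                          verbose = FALSE) {
  sc <- config$sampling
  n_runs <- max(1L, as.integer(sc$n_runs_per_region %||% 1L))
  k <- config$restraint$spring_constant
  sr <- samplingRegions(grid)
  raw <- vector("list", nRegions(grid))
  clipped <- vector("list", nRegions(grid))
  for (i in seq_len(nRegions(grid))) {
    if (is.null(starts[[i]])) {
      if (verbose) message("region ", i, ": no start structure, skipped")
      clipped[[i]] <- list(region_id = i,
                           cv = matrix(numeric(0), 0, 2), L = 0L)
      next
    }
    if (verbose) message("region ", i, "/", nRegions(grid))
    cand <- if (is.list(starts[[i]])) starts[[i]] else list(starts[[i]])
    restraint <- flatBottomRestraint(k, v_min = sr[i, c(1, 3)],
                                     v_max = sr[i, c(2, 4)])
    steps_per_run <- ceiling(sc$n_steps_region / n_runs)
    runs <- vector("list", n_runs)
    cv <- NULL
    for (r in seq_len(n_runs)) {
      start <- cand[[1L + (r - 1L) %% length(cand)]]
      runs[[r]] <- langevinRun(model, start, steps_per_run,
                               restraint = restraint, basis = basis,
                               dt = sc$dt, friction = sc$friction,
                               seed = seed_base + 31L * i + r,
                               save_every = sc$save_every)
      cvr <- cvSeries(runs[[r]])
      burn <- ceiling((sc$burn_frac %||% 0) * nrow(cvr))
      if (burn > 0) cvr <- cvr[-seq_len(burn), , drop = FALSE]
      cv <- rbind(cv, cvr)
    }
    raw[[i]] <- runs
    clipped[[i]] <- clipToRegion(cv, grid, i)
  }
  list(raw = raw, clipped = clipped)
}

#' End-to-end toy demonstration of the divide-and-conquer landscape
#'
#' Builds the bead-chain model, derives the PCA collective variables from
#' an unbiased reference run, partitions the CV plane into overlapping
#' sampling regions, samples each region under its flat-bottom restraint
#' (`repeats` independent replicas with distinct seeds), stitches the
#' per-region samples into a landscape via overlap-count weights, and
#' validates the first replica against a long unbiased reference landscape.
#'
#' @param config configuration list; partial lists are merged over
#'   [defaultRunConfig()].
#' @param seed master seed; every stage derives its own seed from it.
#' @param verbose print stage progress (default FALSE).
#' @return list with elements `model`, `basis`, `grid`, `weights` (first
#'   replica), `fels` (stitched [FELGrid-class] per replica), `oracle`
#'   (reference landscape), `comparison` (first replica vs oracle, see
#'   [compareFel()]), `repeat_spread` (max mean |Delta F| between
#'   replicas), `cv_ref`, and `config`.
#' @export
runDemoPipeline <- function(config = list(), seed = 1L, verbose = FALSE) {
  config <- mergeConfig(defaultRunConfig(), config)
  seed <- as.integer(seed)
  setup <- .pipelineSetup(config, seed, verbose)
  fc <- config$fel
  repeats <- max(1L, as.integer(config$repeats))

  runs <- lapply(seq_len(repeats), function(r)
    sampleRegions(setup$model, setup$basis, setup$grid, setup$starts,
                  config, seed_base = seed + 100L + 1000L * (r - 1L),
                  verbose = verbose))

  all_cv <- do.call(rbind, lapply(runs[[1]]$clipped, function(s) s$cv))
  edges <- chooseBinEdges(all_cv, fc$target_median, fc$max_bins,
                          fc$min_bins)

  weights_list <- vector("list", repeats)
  fels <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    counts <- computeOverlapCounts(runs[[r]]$clipped, setup$grid)
    weights_list[[r]] <- propagateWeights(setup$grid, counts,
                                          convention = config$weights$convention,
                                          method = config$weights$method)
    fels[[r]] <- assembleFel(runs[[r]]$clipped, weights_list[[r]],
                             setup$grid, edges$v1, edges$v2,
                             temperature_K = setup$model@temperature)
  }

  if (verbose) message("oracle run (", config$oracle$n_steps, " steps)")
  oracle <- referenceFelOracle(setup$model, setup$init_coords, setup$basis,
                               edges$v1, edges$v2,
                               n_steps = config$oracle$n_steps,
                               dt = config$sampling$dt,
                               friction = config$sampling$friction,
                               seed = seed + 7777L,
                               save_every = config$sampling$save_every,
                               warn_empty = FALSE)
  comparison <- compareFel(fels[[1]], oracle,
                           min_count = fc$min_compare_count)
  spread <- if (repeats > 1L) {
    max(vapply(seq(2L, repeats), function(r)
      compareFel(fels[[1]], fels[[r]])$mean_abs, numeric(1)))
  } else NA_real_

  list(model = setup$model, basis = setup$basis, grid = setup$grid,
       weights = weights_list[[1]], fels = fels, oracle = oracle,
       comparison = comparison, repeat_spread = spread,
       cv_ref = setup$cv_ref, config = config)
}

#' Write per-region CV sample tables (command-layer helper)
#'
#' Runs the sampling stage and writes, per replica, a CSV table with
#' columns region_id, step, v1, v2 (raw, pre-exclusion samples), plus the
#' region layout and the PCA basis, into `out_dir`.  Real simulation
#' output in the same table format can be substituted for stitching.
#'
#' @param config configuration list or YAML path.
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param verbose print progress.
#' @return paths of the written files, invisibly.
#' @export
cmdSample <- function(config = list(), out_dir = ".", seed = 1L,
                      verbose = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- mergeConfig(defaultRunConfig(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  setup <- .pipelineSetup(config, as.integer(seed), verbose)
  paths <- c(layout = file.path(out_dir, "region_layout.csv"),
             basis = file.path(out_dir, "pca_basis.txt"))
  writeRegionLayout(setup$grid, paths[["layout"]])
  writeBasis(setup$basis, paths[["basis"]])
  repeats <- max(1L, as.integer(config$repeats))
  for (r in seq_len(repeats)) {
    run <- sampleRegions(setup$model, setup$basis, setup$grid,
                         setup$starts, config,
                         seed_base = as.integer(seed) + 100L +
                           1000L * (r - 1L), verbose = verbose)
    tab <- do.call(rbind, lapply(seq_along(run$raw), function(i) {
      if (is.null(run$raw[[i]])) return(NULL)
      do.call(rbind, lapply(run$raw[[i]], function(tr)
        data.frame(region_id = i, step = tr@steps,
                   v1 = tr@cv[, 1], v2 = tr@cv[, 2])))
    }))
    p <- file.path(out_dir, sprintf("cv_samples_rep%d.csv", r))
    write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, setNames(p, sprintf("rep%d", r)))
  }
  invisible(paths)
}

#' Stitch a landscape from CV sample tables (command-layer helper)
#'
#' Reads a region layout and one or more CV sample tables (columns
#' region_id, step, v1, v2), applies the exclusion rule, propagates
#' overlap weights, assembles the landscape per table, and writes
#' `fel.csv`, `weights.csv` and a short report; with several tables the
#' report includes the spread of the landscape across replicas.
#'
#' @param table_paths character vector of CV table CSVs (replicas).
#' @param layout_path region layout CSV (see [writeRegionLayout()]).
#' @param out_dir output directory.
#' @param temperature_K temperature for the Boltzmann inversion.
#' @param config configuration list for binning parameters.
#' @return list with `fels`, `weights`, `spread`, invisibly.
#' @export
cmdStitchFel <- function(table_paths, layout_path, out_dir = ".",
                         temperature_K = 300, config = list()) {
  config <- mergeConfig(defaultRunConfig(), config)
  fc <- config$fel
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- readRegionLayout(layout_path)
  clip_table <- function(path) {
    tab <- read.csv(path)
    lapply(sort(unique(tab$region_id)), function(i)
      clipToRegion(as.matrix(tab[tab$region_id == i, c("v1", "v2")]),
                   grid, i))
  }
  clipped <- lapply(table_paths, clip_table)
  all_cv <- do.call(rbind, lapply(clipped[[1]], function(s) s$cv))
  edges <- chooseBinEdges(all_cv, fc$target_median, fc$max_bins,
                          fc$min_bins)
  fels <- vector("list", length(clipped))
  weights <- vector("list", length(clipped))
  for (r in seq_along(clipped)) {
    counts <- computeOverlapCounts(clipped[[r]], grid)
    weights[[r]] <- propagateWeights(grid, counts)
    fels[[r]] <- assembleFel(clipped[[r]], weights[[r]], grid, edges$v1,
                             edges$v2, temperature_K = temperature_K)
  }
  writeFelGrid(fels[[1]], file.path(out_dir, "fel.csv"))
  W <- regionWeights(weights[[1]])
  write.csv(data.frame(region_id = seq_along(W), W = W,
                       n_edges_used = weights[[1]]@n_edges_used),
            file.path(out_dir, "weights.csv"), row.names = FALSE)
  spread <- if (length(fels) > 1L)
    max(vapply(seq(2L, length(fels)), function(r)
      compareFel(fels[[1]], fels[[r]])$mean_abs, numeric(1)))
  else NA_real_
  writeLines(c(
    sprintf("replicas: %d", length(fels)),
    sprintf("regions: %d (linked: %d)", nRegions(grid),
            sum(weights[[1]]@linked)),
    sprintf("bins: %d x %d", length(edges$v1) - 1L, length(edges$v2) - 1L),
    sprintf("replica spread (mean |dF|, kcal/mol): %s",
            format(spread, digits = 4))),
    file.path(out_dir, "stitch_report.txt"))
  invisible(list(fels = fels, weights = weights, spread = spread))
}

#' PCA of a PDB ensemble (command-layer helper)
#'
#' Reads a multi-model PDB file, restricts it to the analysis atoms,
#' superposes every model on the fit selection of the first model, builds
#' the PCA basis, and writes the basis file plus a per-model projection
#' table.
#'
#' @param pdb_path multi-model PDB file.
#' @param out_basis,out_projections output paths.
#' @param pca_atom,pca_range atom name / residue range analysed by PCA
#'   (default all Calpha atoms).
#' @param fit_atom,fit_range atom name / residue range of the superposition
#'   reference (default: the PCA atoms).
#' @param chain chain to read (default first).
#' @return list with the basis and the projection table, invisibly.
#' @export
cmdPca <- function(pdb_path, out_basis, out_projections, pca_atom = "CA",
                   pca_range = NULL, fit_atom = "CA", fit_range = NULL,
                   chain = NULL) {
  ens <- readPdbEnsemble(pdb_path, chain = chain)
  sub <- subsetEnsemble(ens, selectAtoms(ens, pca_atom, pca_range))
  fit_idx <- selectAtoms(sub, fit_atom, fit_range)
  ref <- fitReference(modelCoords(sub, 1), fit_idx)
  basis <- buildPcaBasis(sub, ref)
  cv <- projectEnsemble(sub, basis, 1:2)
  writeBasis(basis, out_basis, n_components = min(20L, nModels(sub)))
  cv2 <- tryCatch(cumulativeVariance(basis, 2), error = function(e) NA_real_)
  tab <- data.frame(model = seq_len(nModels(sub)), v1 = cv[, 1],
                    v2 = cv[, 2], cumvar2 = cv2)
  write.csv(tab, out_projections, row.names = FALSE)
  invisible(list(basis = basis, projections = tab))
}
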