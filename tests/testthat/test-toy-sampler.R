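test_that("toy model construction is deterministic and validated", {
  a <- buildToyModel(seed = 10)
  b <- buildToyModel(seed = 10)
  expect_identical(a$coords, b$coords)
  expect_false(identical(a$coords, buildToyModel(seed = 11)$coords))
  q <- sqrt(sum((a$coords[10, ] - a$coords[1, ])^2))
  expect_lt(abs(q - (16 - 4)), 1)          # starts in the compact well
  expect_error(buildToyModel(n_beads = 2), "4 beads")
  expect_error(buildToyModel(barrier_h = -1), "unbounded")
})

test_that("trajectories are reproducible under a fixed seed", {
  tm <- buildToyModel(seed = 1)
  t1 <- langevinRun(tm$model, tm$coords, 2000, seed = 5)
  t2 <- langevinRun(tm$model, tm$coords, 2000, seed = 5)
  expect_identical(trajectoryFrames(t1), trajectoryFrames(t2))
  t3 <- langevinRun(tm$model, tm$coords, 2000, seed = 6)
  expect_false(identical(trajectoryFrames(t1), trajectoryFrames(t3)))
})

test_that("the two wells are resolved within the leading principal components", {
  tm <- buildToyModel(seed = 3)
  traj <- langevinRun(tm$model, tm$coords, 200000, seed = 5,
                      save_every = 20)
  ens <- trajectoryToEnsemble(traj)
  ref <- fitReference(modelCoords(ens, 1), 1:10)
  basis <- buildPcaBasis(ens, ref)
  v <- projectEnsemble(ens, basis, 1:2)
  q <- vapply(seq_len(nModels(ens)), function(i) {
    m <- modelCoords(ens, i); sqrt(sum((m[10, ] - m[1, ])^2))
  }, numeric(1))
  # both wells visited, and the well coordinate is carried by the first
  # two components: one of v1, v2 tracks it strongly, and the well
  # centroids are well separated in the CV plane
  expect_gt(mean(q > 16), 0.1); expect_gt(mean(q < 16), 0.1)
  expect_gt(max(abs(cor(v, q))), 0.8)
  expect_gt(cumulativeVariance(basis, 2), 0.7)
  mu_open <- colMeans(v[q > 16, ]); mu_closed <- colMeans(v[q < 16, ])
  spread <- mean(c(apply(v[q > 16, ], 2, sd), apply(v[q < 16, ], 2, sd)))
  expect_gt(sqrt(sum((mu_open - mu_closed)^2)), 1.5 * spread)
})

test_that("unbiased sampling reproduces the exact bond-length density", {
  # with the mode, bending and slab terms off, the Boltzmann density
  # factorises over bond vectors:
  # p(d) proportional to d^2 exp(-k (d - b0)^2 / (2 kT)) exactly
  tm <- buildToyModel(barrier_h = 0, bend_k = 0, plane_k = 0,
                      chiral_k = 0, seed = 2)
  kT <- thermalEnergy(300)
  traj <- langevinRun(tm$model, tm$coords, 400000, dt = 0.005, seed = 8,
                      save_every = 100)
  fr <- trajectoryFrames(traj)
  d <- apply(fr, 1, function(x) {
    m <- matrix(x, ncol = 3, byrow = TRUE)
    sqrt(sum((m[4, ] - m[3, ])^2))
  })
  dens <- function(x) x^2 * exp(-tm$model@bond_k * (x - 3.8)^2 / (2 * kT))
  z <- integrate(dens, 2.5, 5.5)$value
  m1 <- integrate(function(x) x * dens(x), 2.5, 5.5)$value / z
  m2 <- integrate(function(x) x^2 * dens(x), 2.5, 5.5)$value / z
  expect_equal(var(d), m2 - m1^2, tolerance = 0.05)
  expect_equal(mean(d), m1, tolerance = 0.01)

  # chi-square on decile bins of the exact density
  qs <- seq(0.1, 0.9, by = 0.1)
  cdf <- function(x) integrate(dens, 2.5, x)$value / z
  edges <- vapply(qs, function(p) uniroot(function(x) cdf(x) - p,
                                          c(2.5, 5.5))$root, numeric(1))
  obs <- table(cut(d, c(-Inf, edges, Inf)))
  expect_gt(chisq.test(obs)$p.value, 0.01)
})

test_that("the zero-temperature limit descends to the nearest minimum", {
  tm <- buildToyModel(temperature = 0.01, seed = 4)
  traj <- langevinRun(tm$model, tm$coords, 50000, seed = 9)
  final <- matrix(trajectoryFrames(traj)[nrow(trajectoryFrames(traj)), ],
                  ncol = 3, byrow = TRUE)
  # a local minimum of the full potential: forces vanish and the energy
  # has dropped well below the (strained) start
  ef <- toyEnergyForce(tm$model, final)
  expect_lt(max(abs(ef$force)), 0.05)
  expect_lt(ef$energy, toyEnergyForce(tm$model, tm$coords)$energy)
  # the end-to-end distance settles in the compact well (the bond,
  # bending and scaffold terms shift the minimum slightly off q0 - w)
  q <- sqrt(sum((final[10, ] - final[1, ])^2))
  expect_lt(abs(q - 12), 1.0)
})

test_that("a flat-bottom restraint confines the collective variables", {
  tm <- buildToyModel(seed = 3)
  pre <- langevinRun(tm$model, tm$coords, 40000, seed = 12)
  ens <- trajectoryToEnsemble(pre)
  basis <- buildPcaBasis(ens, fitReference(modelCoords(ens, 1), 1:10))
  cvp <- projectEnsemble(ens, basis, 1:2)
  k <- 1
  r <- flatBottomRestraint(k, v_min = apply(cvp, 2, median) - 2,
                           v_max = apply(cvp, 2, median) + 2)
  traj <- langevinRun(tm$model, tm$coords, 120000, restraint = r,
                      basis = basis, seed = 13)
  cv <- cvSeries(traj)
  delta <- 3 * sqrt(thermalEnergy(300) / k)
  inside <- cv[, 1] >= r@v_min[1] - delta & cv[, 1] <= r@v_max[1] + delta &
    cv[, 2] >= r@v_min[2] - delta & cv[, 2] <= r@v_max[2] + delta
  expect_gt(mean(inside), 0.99)
})

test_that("reweighting a restrained run recovers the unbiased density", {
  tm <- buildToyModel(seed = 3)
  long <- langevinRun(tm$model, tm$coords, 400000, seed = 21)
  ens <- trajectoryToEnsemble(long)
  basis <- buildPcaBasis(ens, fitReference(modelCoords(ens, 1), 1:10))
  v1 <- projectEnsemble(ens, basis, 1)[, 1]
  kT <- thermalEnergy(300)

  # box over the well the start structure sits in, so the restrained run
  # equilibrates its interior quickly (no internal barrier)
  q <- vapply(seq_len(nModels(ens)), function(i) {
    m <- modelCoords(ens, i); sqrt(sum((m[10, ] - m[1, ])^2))
  }, numeric(1))
  side <- q < 16                            # compact well, where we start
  box <- quantile(v1[side], c(0.03, 0.97))
  r <- flatBottomRestraint(1, v_min = c(box[1], -50),
                           v_max = c(box[2], 50))
  traj <- langevinRun(tm$model, tm$coords, 400000, restraint = r,
                      basis = basis, seed = 22)
  cv <- cvSeries(traj)
  cv <- cv[-seq_len(nrow(cv) * 0.1), , drop = FALSE]
  phi <- vapply(seq_len(nrow(cv)), function(i)
    flatBottomEnergy(cv[i, ], r), numeric(1))
  wts <- exp(phi / kT)                      # undo the bias

  edges <- seq(quantile(v1[side], 0.1), quantile(v1[side], 0.9),
               length.out = 9)
  hu <- hist(v1, breaks = c(-Inf, edges, Inf), plot = FALSE)$counts
  hb <- vapply(seq_len(length(edges) - 1), function(b) {
    sel <- cv[, 1] >= edges[b] & cv[, 1] < edges[b + 1]
    sum(wts[sel])
  }, numeric(1))
  hu <- hu[2:(length(edges))]               # interior bins only
  ok <- hu > 200 & hb > 200
  expect_gt(sum(ok), 3)
  fu <- -kT * log(hu[ok] / sum(hu[ok]))
  fb <- -kT * log(hb[ok] / sum(hb[ok]))
  expect_lt(mean(abs((fu - mean(fu)) - (fb - mean(fb)))), 0.12)
})

test_that("basin free-energy quadrature reproduces designed well offsets", {
  even <- buildToyModel(seed = 1)$model
  expect_equal(modeBasinDeltaF(even), 0, tolerance = 1e-8)
  tilted <- buildToyModel(delta_u = 0.7, seed = 1)$model
  expect_equal(modeBasinDeltaF(tilted), 0.7, tolerance = 0.1)
})

test_that("the sampling oracle yields a masked, min-shifted landscape", {
  tm <- buildToyModel(seed = 3)
  pre <- langevinRun(tm$model, tm$coords, 60000, seed = 31)
  ens <- trajectoryToEnsemble(pre)
  basis <- buildPcaBasis(ens, fitReference(modelCoords(ens, 1), 1:10))
  cvp <- projectEnsemble(ens, basis, 1:2)
  e1 <- seq(min(cvp[, 1]) - 8, max(cvp[, 1]) + 8, length.out = 25)
  e2 <- seq(min(cvp[, 2]) - 8, max(cvp[, 2]) + 8, length.out = 20)
  expect_warning(
    fel <- referenceFelOracle(tm$model, tm$coords, basis, e1, e2,
                              n_steps = 100000, seed = 32),
    "masked")
  vals <- felMatrix(fel)[!fel@mask]
  expect_equal(min(vals), 0)
  expect_true(any(fel@mask))               # padded corners are empty
  expect_true(all(is.na(felMatrix(fel)[fel@mask])))
})

test_that("integration blow-up is reported with the failing step", {
  tm <- buildToyModel(seed = 1)
  expect_error(langevinRun(tm$model, tm$coords * 50, 1000, dt = 10,
                           seed = 2, blowup = 100),
               "diverged at step")
})
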