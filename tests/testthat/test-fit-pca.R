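test_that("crossCovariance matches direct arithmetic and ignores translation", {
  r <- matrix(c(0, 0, 0, 1, 0, 0, 0, 2, 0, 1, 1, 3), 4, 3, byrow = TRUE)
  s <- matrix(c(0, 1, 0, 2, 0, 0, 0, 0, 1, 1, 2, 1), 4, 3, byrow = TRUE)
  ref <- fitReference(s, 1:4)
  A <- crossCovariance(r, ref)
  # hand evaluation of A_ab = sum (r - Q)_a (s - P)_b
  Q <- colMeans(r); P <- colMeans(s)
  A_hand <- matrix(0, 3, 3)
  for (nu in 1:4)
    A_hand <- A_hand + outer(r[nu, ] - Q, s[nu, ] - P)
  expect_equal(A, A_hand, tolerance = 1e-12)
  expect_equal(crossCovariance(sweep(r, 2, c(-10, 0, 4)), ref), A,
               tolerance = 1e-12)
  # self cross-covariance is the symmetric PSD scatter matrix
  A_self <- crossCovariance(s, ref)
  expect_equal(A_self, t(A_self), tolerance = 1e-12)
  expect_true(all(eigen(A_self, symmetric = TRUE)$values > -1e-12))
  expect_error(crossCovariance(r[1:2, ], fitReference(s[1:3, ], 1:3)), ".")
})

test_that("optimalRotation recovers known rotations and stays proper", {
  set.seed(21)
  X <- matrix(rnorm(18, sd = 3), 6, 3)
  ref <- fitReference(X, 1:6)
  expect_equal(fitModel(X, ref)$R, diag(3), tolerance = 1e-10)

  R0 <- rot_z(pi / 6)
  fit <- fitModel(X %*% t(R0), ref)            # model = R0 applied to ref
  expect_equal(fit$R %*% R0, diag(3), tolerance = 1e-10)
  expect_equal(det(fit$R), 1, tolerance = 1e-10)

  # reflected configuration still yields a proper rotation
  Xr <- X; Xr[, 1] <- -Xr[, 1]
  A <- crossCovariance(Xr, ref)
  expect_lt(det(A), 0)
  R <- optimalRotation(A)
  expect_equal(det(R), 1, tolerance = 1e-10)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-10)

  # collinear fit atoms are a degeneracy
  line <- cbind(1:4, 0, 0)
  expect_error(fitModel(line, fitReference(line, 1:4)), "collinear")
})

test_that("optimalRotation equals (A^t A)^(1/2) A^(-1) when det(A) > 0", {
  set.seed(8)
  for (i in 1:5) {
    A <- matrix(rnorm(9), 3, 3)
    if (det(A) < 0) A[, 1] <- -A[, 1]
    e <- eigen(crossprod(A), symmetric = TRUE)
    sqrtAtA <- e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
    expect_equal(optimalRotation(A), sqrtAtA %*% solve(A),
                 tolerance = 1e-8)
  }
})

test_that("fitting removes rigid motion exactly and is optimal over rotations", {
  set.seed(31)
  X <- matrix(rnorm(24, sd = 3), 8, 3)
  ref <- fitReference(X, 1:8)
  moved <- X %*% t(random_rotation()) +
    matrix(rep(c(7, -3, 2), each = 8), 8, 3)
  fit <- fitModel(moved, ref)
  target <- sweep(X, 2, ref@centroid)
  expect_lt(sqrt(mean(rowSums((fit$fitted - target)^2))), 1e-10)

  # random-rotation oracle: no tested rotation beats the analytic optimum
  pert <- moved + matrix(rnorm(24, sd = 0.8), 8, 3)
  fitp <- fitModel(pert, ref)
  best <- sqrt(mean(rowSums((fitp$fitted - target)^2)))
  ctr <- sweep(pert, 2, colMeans(pert))
  for (k in 1:100) {
    trial <- sqrt(mean(rowSums((ctr %*% t(random_rotation()) - target)^2)))
    expect_gte(trial, best - 1e-10)
  }
})

test_that("fitted coordinates are invariant to rigid motion of the input", {
  set.seed(5)
  ens <- random_ensemble(7, 3, seed = 13)
  ref <- fitReference(modelCoords(ens, 1), 1:7)
  X <- modelCoords(ens, 2)
  f1 <- fitModel(X, ref)$fitted
  f2 <- fitModel(X %*% t(random_rotation()) +
                   matrix(rep(c(-4, 9, 1), each = 7), 7, 3), ref)$fitted
  expect_lt(max(abs(f1 - f2)), 1e-8)
})

test_that("PCA basis has the designed rank and spectrum", {
  # identical models: zero spectrum
  X <- matrix(rnorm(15, sd = 2), 5, 3)
  same <- conformationEnsemble(list(X, X, X), ca_atoms(5))
  ref <- fitReference(X, 1:5)
  b0 <- buildPcaBasis(same, ref)
  expect_lt(max(basisEigenvalues(b0)), 1e-12)
  expect_error(cumulativeVariance(b0, 1), "all-zero")

  # two models: exactly one nonzero eigenvalue
  two <- mode_ensemble(c(-1, 1), n_atoms = 6, n_fit = 3)
  ref2 <- fitReference(two$core, two$fit_idx)
  b2 <- buildPcaBasis(two$ens, ref2)
  lam <- basisEigenvalues(b2)
  expect_gt(lam[1], 0.5)
  expect_lt(lam[2] / lam[1], 1e-10)

  expect_error(buildPcaBasis(conformationEnsemble(list(X), ca_atoms(5)),
                             ref), "at least 2")
})

test_that("a constructed displacement mode is recovered as the first component", {
  a <- c(-2, -1, 0, 1, 2, 3, -3)
  fx <- mode_ensemble(a, n_atoms = 9, n_fit = 4, seed = 9)
  ref <- fitReference(fx$core, fx$fit_idx)
  basis <- buildPcaBasis(fx$ens, ref)
  lam <- basisEigenvalues(basis)
  expect_equal(lam[1], mean((a - mean(a))^2), tolerance = 1e-8)
  expect_lt(lam[2], 1e-10)
  expect_equal(cumulativeVariance(basis, 1), 1, tolerance = 1e-10)
  # projections reproduce the centred amplitudes (up to one global sign)
  v <- projectEnsemble(fx$ens, basis, 1:2)
  sgn <- sign(sum(v[, 1] * (a - mean(a))))
  expect_equal(sgn * v[, 1], a - mean(a), tolerance = 1e-8)
  expect_lt(max(abs(v[, 2])), 1e-8)
})

test_that("training projections are centred with variance lambda_n", {
  ens <- random_ensemble(8, 12, sd = 1, seed = 17)
  ref <- fitReference(modelCoords(ens, 1), 1:8)
  basis <- buildPcaBasis(ens, ref)
  v <- projectEnsemble(ens, basis, 1:4)
  expect_lt(max(abs(colMeans(v))), 1e-10)
  lam <- basisEigenvalues(basis)[1:4]
  expect_equal(colMeans(v^2), lam, tolerance = 1e-8)
})

test_that("buildPcaBasis matches a brute-force covariance + eigen oracle", {
  ens <- random_ensemble(6, 9, sd = 1.2, seed = 23)
  ref <- fitReference(modelCoords(ens, 1), 1:6)
  basis <- buildPcaBasis(ens, ref)
  # independent route: fit every model, covariance by explicit loops
  flat <- t(sapply(seq_len(nModels(ens)), function(i)
    as.vector(t(fitModel(modelCoords(ens, i), ref)$fitted))))
  mu <- colMeans(flat)
  M <- nrow(flat); D <- ncol(flat)
  covm <- matrix(0, D, D)
  for (i in seq_len(M))
    covm <- covm + tcrossprod(flat[i, ] - mu) / M
  e <- eigen(covm, symmetric = TRUE)
  expect_equal(basisEigenvalues(basis), pmax(e$values, 0), tolerance = 1e-8)
  for (k in 1:3)
    expect_equal(abs(sum(basisEigenvectors(basis)[, k] * e$vectors[, k])),
                 1, tolerance = 1e-8)
})

test_that("cumulativeVariance follows the spectrum", {
  ref <- fitReference(matrix(rnorm(9), 3, 3), 1:3)
  vecs <- qr.Q(qr(matrix(rnorm(81), 9, 9)))[, 1:4]
  basis <- new("PCABasis", mean_coords = numeric(9), eigenvectors = vecs,
               eigenvalues = c(4, 3, 2, 1), fit_reference = ref,
               centered = TRUE)
  expect_equal(cumulativeVariance(basis, 2), 0.7)
  expect_equal(cumulativeVariance(basis, 4), 1.0)
  expect_error(cumulativeVariance(basis, 5), "exceeds")
})

test_that("basis serialisation round-trips and porcupine export is complete", {
  ens <- random_ensemble(5, 6, seed = 29)
  ref <- fitReference(modelCoords(ens, 1), 1:5)
  basis <- buildPcaBasis(ens, ref)
  f <- withr::local_tempfile(fileext = ".txt")
  writeBasis(basis, f)
  rt <- readBasis(f)
  expect_equal(rt@mean_coords, basis@mean_coords)
  expect_equal(rt@eigenvalues, basis@eigenvalues)
  expect_equal(rt@eigenvectors, basis@eigenvectors)
  expect_equal(rt@fit_reference@fit_indices, ref@fit_indices)
  X <- modelCoords(ens, 3)
  expect_equal(projectCV(X, rt, 1:2), projectCV(X, basis, 1:2))

  p <- withr::local_tempfile(fileext = ".csv")
  tab <- writePorcupine(basis, p, components = 1:2)
  expect_equal(nrow(tab), 5L)
  expect_true(all(c("dx1", "dz2") %in% names(tab)))
})
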