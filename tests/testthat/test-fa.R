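# Factor-model estimation: standardization, regularization, extraction,
# target rotation, confirmatory fits and fit indices.

plant_cfa <- function(P = 24, K = 3, seed = 1, phi = NULL) {
  set.seed(seed)
  labels <- rep(seq_len(K), length.out = P)[order(rep(seq_len(K), length.out = P))]
  lam <- runif(P, 0.4, 0.8)
  L <- matrix(0, P, K); L[cbind(seq_len(P), labels)] <- lam
  if (is.null(phi)) {
    phi <- diag(K)
    phi[upper.tri(phi)] <- runif(K * (K - 1) / 2, 0.1, 0.4)
    phi[lower.tri(phi)] <- t(phi)[lower.tri(phi)]
  }
  psi <- 1 - diag(L %*% phi %*% t(L))
  R <- L %*% phi %*% t(L) + diag(psi)
  list(L = L, phi = phi, psi = psi, R = R, labels = labels)
}

test_that("standardization yields unit-variance columns and their correlation", {
  set.seed(2)
  X <- matrix(rnorm(400), 100, 4) %*% matrix(rnorm(16), 4)
  st <- standardize_timeseries(X)
  expect_lt(max(abs(colMeans(st$X))), 1e-12)
  expect_lt(max(abs(apply(st$X, 2, sd) - 1)), 1e-12)
  # idempotent on already standardized input
  st2 <- standardize_timeseries(st$X)
  expect_lt(max(abs(st2$X - st$X)), 1e-12)
  # two identical columns correlate at exactly 1
  Y <- cbind(X[, 1], X[, 1], X[, 2])
  expect_equal(standardize_timeseries(Y)$R[1, 2], 1)
  expect_error(standardize_timeseries(cbind(X[, 1], rep(2, 100))), "constant")
  # law of large numbers: sample correlation approaches the truth
  set.seed(3)
  sig <- matrix(c(1, .6, .3, .6, 1, .1, .3, .1, 1), 3)
  Xl <- matrix(rnorm(3e5), 1e5, 3) %*% chol(sig)
  expect_lt(max(abs(standardize_timeseries(Xl)$R - sig)), 0.02)
})

test_that("ridge regularization rescales correlations and restores definiteness", {
  R <- matrix(c(1, 0.505, 0.505, 1), 2)
  out <- regularize_correlation(R, 0.01)
  expect_equal(out[1, 2], 0.5)
  expect_equal(regularize_correlation(R, 0), R, ignore_attr = TRUE)
  # rank-deficient matrix from N < P series becomes PD, structure preserved
  set.seed(4)
  X <- matrix(rnorm(8 * 12), 8, 12)
  Rdef <- suppressWarnings(standardize_timeseries(X)$R)
  out2 <- regularize_correlation(Rdef, 0.01)
  ev <- eigen(out2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(cor(Rdef[upper.tri(Rdef)], out2[upper.tri(out2)]), 1)
})

test_that("the implied correlation respects the decomposition and rotation invariance", {
  pl <- plant_cfa()
  expect_equal(implied_sigma(matrix(0, 6, 2), diag(2), rep(0.7, 6)),
               diag(0.7, 6))
  sig <- implied_sigma(pl$L, pl$phi, pl$psi)
  expect_lt(max(abs(diag(sig) - 1)), 1e-12)   # uniqueness = 1 - communality
  # orthonormal rotation leaves the implied matrix unchanged
  set.seed(5)
  Tm <- qr.Q(qr(matrix(rnorm(9), 3)))
  sig2 <- implied_sigma(pl$L %*% Tm, t(Tm) %*% pl$phi %*% Tm, pl$psi)
  expect_lt(max(abs(sig - sig2)), 1e-10)
})

test_that("ML extraction recovers planted orthogonal-factor structure", {
  set.seed(6)
  P <- 12
  lam <- runif(P, 0.4, 0.85)
  R <- lam %o% lam; diag(R) <- 1
  efa <- fit_efa(R, 1, 500)
  expect_true(efa$converged)
  expect_lt(max(abs(abs(efa$loadings[, 1]) - lam)), 1e-4)
  expect_lt(max(abs(efa$uniqueness - (1 - lam^2))), 1e-4)
  # identity input: no common variance in the implied matrix (the loading
  # direction is not identified when a uniqueness sits at its upper bound,
  # but the implied correlation must still be the identity)
  efa0 <- fit_efa(diag(8), 1, 100)
  expect_lt(max(abs(implied_sigma(efa0) - diag(8))), 1e-6)
  expect_gt(min(efa0$uniqueness), 0.9)
})

test_that("target rotation recovers a planted oblique solution exactly", {
  pl <- plant_cfa(P = 24, K = 3, seed = 7)
  set.seed(8)
  Tm <- qr.Q(qr(matrix(rnorm(9), 3)))
  L0 <- pl$L %*% Tm
  # real-valued target: the criterion is zero at the planted matrix
  rot <- target_rotate(L0, target = pl$L)
  expect_lt(max(abs(rot$loadings - pl$L)), 1e-4)
  expect_lt(rot$criterion, 1e-8)
  # binary cluster-pattern target: structure recovered (cross-loadings die)
  B <- (pl$L != 0) * 1
  rot2 <- target_rotate(L0, target = B)
  expect_lt(max(abs(rot2$loadings[B == 0])), 1e-4)
  expect_gt(min(rot2$loadings[B == 1]), 0.3)
  # the implied common part is invariant under the rotation
  C0 <- L0 %*% t(L0)
  C2 <- rot2$loadings %*% rot2$phi %*% t(rot2$loadings)
  expect_lt(max(abs(C0 - C2)), 1e-8)
})

test_that("rotation criterion never beats the identity start by accident", {
  # the multi-start winner must be at least as good as the identity start
  pl <- plant_cfa(P = 18, K = 3, seed = 9)
  set.seed(10)
  X <- generate_functional_data(pl$L, pl$phi, 300)
  R <- standardize_timeseries(X)$R
  efa <- fit_efa(R, 3, 300)
  B <- (pl$L != 0) * 1
  W <- (B == 0) * 1
  rot <- target_rotate(efa, B)
  f_id <- sum(W * (efa$loadings - B)^2)
  expect_lte(rot$criterion, f_id + 1e-8)
})

test_that("confirmatory fits recover planted parameters from exact input", {
  pl <- plant_cfa(P = 24, K = 3, seed = 11)
  cfa <- fit_cfa(pl$R, pl$labels, n = 400)
  expect_true(cfa$converged)
  expect_lt(max(abs(cfa$loadings - pl$L)), 1e-4)
  expect_lt(max(abs(cfa$phi - pl$phi)), 1e-4)
  expect_lt(max(abs(cfa$uniqueness - pl$psi)), 1e-4)
  expect_lt(fit_indices(pl$R, cfa, 400)$srmr, 1e-5)
})

test_that("a one-factor three-variable model matches its algebraic solution", {
  r12 <- 0.42; r13 <- 0.3; r23 <- 0.35
  R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
  cfa <- fit_cfa(R, c(1, 1, 1), n = 200)
  l1 <- sqrt(r12 * r13 / r23)
  l2 <- sqrt(r12 * r23 / r13)
  l3 <- sqrt(r13 * r23 / r12)
  expect_equal(unname(cfa$loadings[, 1]), c(l1, l2, l3), tolerance = 1e-5)
})

test_that("estimation pathologies are flagged, not fatal", {
  # a variable with communality ~ 1 drives its uniqueness to the floor
  set.seed(12)
  P <- 9
  lam <- c(0.9995, runif(P - 1, 0.4, 0.7))
  R <- lam %o% lam; diag(R) <- 1
  cfa <- fit_cfa(R, rep(1, P), n = 100)
  expect_s3_class(cfa, "fa_fit")
  expect_true("Heywood" %in% cfa$warnings || min(cfa$uniqueness) < 2e-3)
})

test_that("fit indices match hand arithmetic and perfect-fit limits", {
  pl <- plant_cfa(P = 12, K = 2, seed = 13)
  cfa <- fit_cfa(pl$R, pl$labels, n = 300)
  idx <- fit_indices(pl$R, cfa, 300)
  expect_lt(idx$srmr, 1e-5)
  expect_equal(idx$rmsea, 0, tolerance = 1e-6)
  # hand-computed 3x3 residual example (model with known implied matrix)
  R <- matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3)
  model <- make_fa_fit(
    loadings = matrix(c(.7, .7, .5), 3, 1), phi = diag(1),
    uniqueness = c(1 - .49, 1 - .49, 1 - .25), mode = "efa", R = R, n = 100)
  idx2 <- fit_indices(R, model, 100)
  resid <- c(.5 - .49, .2 - .35, .4 - .35)
  expect_equal(idx2$srmr, sqrt(mean(resid^2)), tolerance = 1e-12)
  # degrees of freedom follow the stated conventions
  expect_equal(idx2$df, ((3 - 1)^2 - (3 + 1)) / 2)
  idxc <- fit_indices(pl$R, cfa, 300)
  expect_equal(idxc$df, 12 * 13 / 2 - (12 + 2 * 1 / 2 + 12))
})

test_that("the top-level factor fit wires pattern, rotation and indices together", {
  pl <- plant_cfa(P = 20, K = 2, seed = 14)
  set.seed(15)
  X <- generate_functional_data(pl$L, pl$phi, 400)
  R <- standardize_timeseries(X)$R
  for (mode in c("efa", "cfa")) {
    fit <- factor_coactivation(R, pl$labels, 400, mode = mode)
    expect_s3_class(fit, "fa_fit")
    expect_equal(dim(fit$loadings), c(20L, 2L))
    expect_true(is.finite(fit$fit$srmr))
    expect_lt(fit$fit$srmr, 0.08)       # comfortably a good fit
    expect_lt(abs(fit$phi[1, 2] - pl$phi[1, 2]), 0.15)
  }
})
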