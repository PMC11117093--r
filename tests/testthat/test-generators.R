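# Synthetic-data generators for the structural and functional conditions.

test_that("structural conditions produce the advertised graph structure", {
  set.seed(1)
  # single: one cluster, fully connected
  tr <- make_structural_truth(structural_condition("single",
                                                   cluster_sizes = c(4, 4)))
  expect_equal(unique(tr$labels), 1)
  expect_true(all(tr$G[upper.tri(tr$G)] == 1))
  expect_true(all(diag(tr$G) == 0))
  expect_equal(tr$rho, matrix(1, 1, 1))
  # independent: diagonal rho, no between-cluster edges
  tr2 <- make_structural_truth(structural_condition("independent",
                                                    cluster_sizes = c(5, 6)))
  expect_true(all(tr2$rho[upper.tri(tr2$rho)] == 0))
  between <- tr2$G[tr2$labels == 1, tr2$labels == 2]
  expect_true(all(between == 0))
  # random conditions: entries in (0, 1), symmetric graph
  tr3 <- make_structural_truth(structural_condition("random_beta_11",
                                                    cluster_sizes = c(4, 4, 4)))
  expect_true(all(tr3$rho > 0 & tr3$rho < 1))
  expect_identical(tr3$G, t(tr3$G))
  expect_error(make_structural_truth(
    structure(list(name = "single", P = 10, cluster_sizes = c(3L, 3L),
                   streamlines_per_row = 100), class = "structural_condition")),
    "sum")
})

test_that("the data-informed surrogate has empirical-like structure", {
  set.seed(2)
  rho <- make_structural_truth(structural_condition("data_informed"))$rho
  expect_equal(nrow(rho), 14)
  expect_true(all(diag(rho) >= 0.75 & diag(rho) <= 0.98))
  off <- rho[upper.tri(rho)]
  frac_big <- mean(off > 0.3)
  expect_gt(frac_big, 0.1); expect_lt(frac_big, 0.3)
  # correlation form is positive definite (needed downstream)
  D <- diag(1 / sqrt(diag(rho)))
  ev <- eigen(D %*% rho %*% D, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("streamline sampling respects totals, diagonal and edge contrast", {
  set.seed(3)
  G <- matrix(0L, 20, 20)
  G[1:10, 1:10] <- 1L
  diag(G) <- 0L
  S <- generate_streamlines(G, per_row_total = 5000)
  expect_true(all(rowSums(S) == 5000))
  expect_true(all(diag(S) == 0))
  # mean count on edge cells vs non-edge cells reflects the delta ratio
  edge_mean <- mean(S[1:10, 1:10][G[1:10, 1:10] == 1])
  non_mean <- mean(S[1:10, 11:20])
  expect_gt(edge_mean / non_mean, 5)    # delta1/delta0 = 10 up to noise
  # flat deltas make cells exchangeable
  S2 <- generate_streamlines(G, delta0 = 1, delta1 = 1 + 1e-9,
                             per_row_total = 50000)
  expect_lt(abs(mean(S2[1, 2:10]) - mean(S2[1, 11:20])) /
              mean(S2[1, -1]), 0.35)
})

test_that("loadings follow the within-cluster connectivity rule", {
  set.seed(4)
  labels <- rep(1:2, c(200, 150))
  rho <- diag(c(0.5, 0.8))
  L <- make_loadings(labels, rho)
  expect_true(all(L[cbind(seq_along(labels), labels)] > 0))
  expect_true(all(L[labels == 1, 2] == 0))
  expect_true(all(L[labels == 2, 1] == 0))
  l1 <- L[labels == 1, 1]
  expect_lt(abs(mean(l1) - 0.5), 3 * 0.05 / sqrt(200))
  expect_lt(abs(sd(l1) - 0.05), 0.015)
})

test_that("factor-correlation conditions generate their advertised patterns", {
  set.seed(5)
  rho <- make_structural_truth(structural_condition("data_informed"))$rho
  expect_equal(make_phi("independent", K = 5), diag(5))
  rphi <- make_phi("random", K = 8)
  expect_true(all(abs(rphi[upper.tri(rphi)]) <= 0.6))
  expect_true(irmfa:::is_pd(rphi))
  p1 <- make_phi("practical1", rho = rho)
  expect_true(irmfa:::is_pd(p1))
  # practical 1 mirrors the structural connectivity in correlation form
  expect_gt(cor(rho[lower.tri(rho)], p1[lower.tri(p1)]), 0.9)
  p2 <- make_phi("practical2", rho = rho)
  expect_true(irmfa:::is_pd(p2))
  # strong structural pairs become weak-to-moderate inverse coactivations
  big <- rho > 0.3 & upper.tri(rho)
  expect_gt(mean(p2[big]), 0.2)
  expect_lt(mean(abs(p2[!big & upper.tri(rho)])), 0.1)
  p3 <- make_phi("practical3", rho = rho)
  expect_true(irmfa:::is_pd(p3))
  # inverted: noise-level structural pairs carry the larger coactivations
  expect_gt(mean(p3[!big & upper.tri(rho)]), mean(p3[big]) + 0.05)
  expect_true(all(abs(p3[upper.tri(p3)]) < 1))
})

test_that("functional data matches its generating correlation matrix", {
  set.seed(6)
  labels <- rep(1:3, each = 5)
  rho <- diag(c(0.6, 0.7, 0.8))
  L <- make_loadings(labels, rho)
  phi <- diag(3); phi[1, 2] <- phi[2, 1] <- 0.3
  sigma <- L %*% phi %*% t(L)
  psi <- 1 - diag(sigma)
  sigma <- sigma + diag(psi)
  expect_lt(max(abs(diag(sigma) - 1)), 1e-12)
  X <- generate_functional_data(L, phi, 1e5)
  expect_lt(max(abs(standardize_timeseries(X)$R - sigma)), 0.02)
  # zero loadings give iid columns
  X0 <- generate_functional_data(matrix(0, 6, 2), diag(2), 5e4)
  R0 <- standardize_timeseries(X0)$R
  expect_lt(max(abs(R0 - diag(6))), 0.03)
  # invalid communality is rejected
  L_bad <- matrix(0, 4, 1); L_bad[, 1] <- c(1.01, 0.5, 0.5, 0.5)
  expect_error(generate_functional_data(L_bad, diag(1), 10), "communality")
})
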