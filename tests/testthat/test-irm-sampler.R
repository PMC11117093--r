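# Validation of the MCMC kernels against exhaustive enumeration on tiny
# problems, plus the summary operations on posterior samples.

make_tiny_problem <- function(P = 4, seed = 2) {
  set.seed(seed)
  labels <- rep(1:2, length.out = P)
  G <- outer(labels, labels, "==") * 1L
  diag(G) <- 0L
  S <- generate_streamlines(G, per_row_total = 40)
  list(S = S, G = G, labels = labels)
}

test_that("incremental caches agree with from-scratch recomputation", {
  pr <- make_tiny_problem(8, seed = 3)
  for (mode in 0:3) {
    set.seed(mode + 1)
    err <- irmfa:::cpp_consistency_check(pr$S, pr$G, pr$labels, log(8),
                                         1, 1, 0.1, 1, 40, mode)
    expect_lt(err, 1e-8)
  }
})

test_that("flat likelihood and uniform prior leave edges at probability 1/2", {
  # delta1 = delta0 makes the DM likelihood edge-free; with alpha = beta = 1
  # every pair's stationary edge probability is 1/2
  pr <- make_tiny_problem(4)
  set.seed(10)
  G <- pr$G
  freq <- matrix(0, 4, 4)
  n <- 3000
  for (t in seq_len(n)) {
    G <- irm_graph_sweep(pr$S, G, pr$labels,
                         run_config(xi = 1, delta0 = 0.5, delta1 = 0.500001))$G
    freq <- freq + G
  }
  p <- freq[upper.tri(freq)] / n
  expect_true(all(abs(p - 0.5) < 3 * sqrt(0.25 / n) * 6))
})

test_that("graph sampler matches exhaustive enumeration on a 4-node problem", {
  pr <- make_tiny_problem(4)
  xi <- log(4)
  en <- enumerate_posterior(pr$S, xi)
  set.seed(42)
  res <- irmfa:::cpp_irm_mcmc(pr$S, pr$G, pr$labels, xi, 1, 1, 0.1, 1,
                              60000, 5000, 3, 0)
  # edge and coassignment marginals within ~3 Monte Carlo standard errors;
  # with 55k retained sweeps and short autocorrelation the binomial se with a
  # x10 effective-sample deflation is below 0.01, so the bound is 0.03
  ut <- upper.tri(en$edge_marginal)
  expect_lt(max(abs(res$G_mean[ut] - en$edge_marginal[ut])), 0.03)
  expect_lt(max(abs(res$M_mean[ut] - en$coassign_marginal[ut])), 0.03)
  # cluster-count distribution
  kk <- tabulate(apply(res$labels, 1, max), nbins = 4) / nrow(res$labels)
  expect_lt(max(abs(kk - en$pK)), 0.03)
})

test_that("Gibbs partition updates match enumeration for a fixed graph", {
  # 5-node fixed graph; chain over partitions only
  set.seed(8)
  P <- 5
  G <- matrix(0L, P, P)
  G[1, 2] <- G[2, 1] <- 1L; G[2, 3] <- G[3, 2] <- 1L
  G[4, 5] <- G[5, 4] <- 1L; G[1, 3] <- G[3, 1] <- 1L
  xi <- 1
  en <- enumerate_partition_posterior(G, xi)
  S0 <- matrix(0, P, P); S0[1, 2] <- 1   # likelihood-free: flat deltas
  cfg <- run_config(xi = xi, delta0 = 0.5, delta1 = 0.5000001)
  for (use_sm in c(FALSE, TRUE)) {
    z <- rep(1L, P)
    n <- 20000
    co <- matrix(0, P, P)
    pk <- numeric(P)
    for (t in seq_len(n)) {
      z <- irm_gibbs_sweep(S0, G, z, cfg)$labels
      if (use_sm) z <- irm_split_merge(S0, G, z, cfg)$labels
      co <- co + outer(z, z, "==")
      pk[max(z)] <- pk[max(z)] + 1
    }
    co <- co / n; pk <- pk / n
    expect_lt(max(abs(co[upper.tri(co)] -
                        en$coassign_marginal[upper.tri(co)])), 0.025)
    expect_lt(max(abs(pk - en$pK)), 0.025)
  }
})

test_that("split-merge alone is a valid kernel for the partition posterior", {
  set.seed(12)
  P <- 5
  G <- matrix(0L, P, P)
  G[1, 2] <- G[2, 1] <- 1L; G[1, 3] <- G[3, 1] <- 1L; G[2, 3] <- G[3, 2] <- 1L
  xi <- 1.5
  en <- enumerate_partition_posterior(G, xi)
  S0 <- matrix(0, P, P); S0[1, 2] <- 1
  cfg <- run_config(xi = xi, delta0 = 0.5, delta1 = 0.5000001)
  z <- seq_len(P)                       # start from all singletons
  n <- 40000
  co <- matrix(0, P, P); pk <- numeric(P)
  for (t in seq_len(n)) {
    z <- irm_split_merge(S0, G, z, cfg)$labels
    co <- co + outer(z, z, "=="); pk[max(z)] <- pk[max(z)] + 1
  }
  co <- co / n; pk <- pk / n
  expect_lt(max(abs(co[upper.tri(co)] -
                      en$coassign_marginal[upper.tri(co)])), 0.03)
  expect_lt(max(abs(pk - en$pK)), 0.03)
})

test_that("strong count evidence keeps well-supported edges near certainty", {
  # counts generated from a fully connected graph at a large total with
  # delta1 >> delta0: the likelihood dominates and every edge stays on
  set.seed(3)
  P <- 6
  G_true <- matrix(1L, P, P); diag(G_true) <- 0L
  S <- generate_streamlines(G_true, per_row_total = 5000)
  G <- matrix(0L, P, P)                 # adversarial start: empty graph
  z <- rep(1L, P)
  cfg <- run_config(xi = 1)
  freq <- matrix(0, P, P)
  for (t in 1:300) {
    G <- irm_graph_sweep(S, G, z, cfg)$G
    if (t > 100) freq <- freq + G
  }
  p <- freq / 200
  # the pair with the strongest count support is (essentially) certain; the
  # average pair is recovered (a pair can draw a small Dirichlet weight and
  # stay genuinely ambiguous)
  tot <- S + t(S)
  best <- which(tot == max(tot), arr.ind = TRUE)[1, ]
  expect_gt(p[best[1], best[2]], 0.99)
  expect_gt(mean(p[upper.tri(p)]), 0.9)
})

test_that("small two-block problems are recovered end to end", {
  set.seed(21)
  truth <- make_structural_truth(
    structural_condition("independent", cluster_sizes = c(5, 5)),
    rho = diag(c(0.95, 0.95)))
  S <- generate_streamlines(truth$G, per_row_total = 2000)
  fit <- suppressWarnings(
    irm(S, run_config(iterations = 400, burnin = 200, chains = 2, seed = 5)))
  expect_equal(fit$partition$K, 2)
  mt <- match_clusters(truth$labels, fit$partition$labels)
  expect_equal(sum(mt$pairs$overlap), 10)   # every ROI correctly grouped
  conf <- edge_confusion(truth$G, fit$G_map)
  expect_gt(conf$hit, 0.9)
})

test_that("fits are reproducible from the configuration seed", {
  set.seed(77)
  truth <- make_structural_truth(
    structural_condition("independent", cluster_sizes = c(4, 4)))
  S <- generate_streamlines(truth$G, per_row_total = 500)
  cfg <- run_config(iterations = 120, burnin = 60, chains = 1, seed = 99)
  f1 <- suppressWarnings(irm(S, cfg))
  f2 <- suppressWarnings(irm(S, cfg))
  expect_identical(f1$G_map, f2$G_map)
  expect_identical(f1$partition$labels, f2$partition$labels)
  expect_identical(f1$chains[[1]]$log_post, f2$chains[[1]]$log_post)
})

test_that("coassignment summaries follow the entrywise-mode rule", {
  # degenerate posterior: every sample identical
  lab <- matrix(rep(c(1L, 1L, 2L), each = 1), nrow = 5, ncol = 3, byrow = TRUE)
  cm <- coassignment_map(lab)
  expect_equal(cm$M_map, outer(c(1, 1, 2), c(1, 1, 2), "==") * 1L)
  # 60% coassignment -> 1; exactly 50% -> 1 (ties resolve up)
  lab2 <- rbind(matrix(rep(c(1L, 1L), 3), 3, 2, byrow = TRUE),
                matrix(rep(c(1L, 2L), 2), 2, 2, byrow = TRUE))
  expect_equal(coassignment_map(lab2)$M_map[1, 2], 1)
  lab3 <- rbind(matrix(rep(c(1L, 1L), 2), 2, 2, byrow = TRUE),
                matrix(rep(c(1L, 2L), 2), 2, 2, byrow = TRUE))
  expect_equal(coassignment_map(lab3)$M_mean[1, 2], 0.5)
  expect_equal(coassignment_map(lab3)$M_map[1, 2], 1)
})

test_that("coassignment decomposition handles block, identity and non-transitive inputs", {
  M <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  out <- decompose_coassignment(M)
  expect_equal(out$K, 2)
  expect_equal(out$labels, c(1, 1, 2, 2))
  expect_equal(out$violations, 0)

  out2 <- decompose_coassignment(diag(4))
  expect_equal(out2$K, 4)

  # chain 1-2, 2-3 without 1-3: ROI 3 joins via its assigned partner
  M3 <- diag(3); M3[1, 2] <- M3[2, 1] <- 1; M3[2, 3] <- M3[3, 2] <- 1
  expect_warning(out3 <- decompose_coassignment(M3), "not transitive")
  expect_equal(out3$labels, c(1, 1, 1))
  expect_equal(out3$violations, 1)
})

test_that("posterior predictive counts have the right structure and mean", {
  set.seed(14)
  truth <- make_structural_truth(
    structural_condition("independent", cluster_sizes = c(4, 4)))
  S <- generate_streamlines(truth$G, per_row_total = 1000)
  fit <- suppressWarnings(
    irm(S, run_config(iterations = 150, burnin = 75, chains = 1, seed = 3)))
  pred <- posterior_predictive_streamlines(fit, n_draws = 50)
  expect_equal(unname(rowSums(pred)), unname(fit$row_totals), tolerance = 1e-9)
  expect_true(all(diag(pred) == 0))
  # zero row total -> zero predicted row
  pred0 <- posterior_predictive_streamlines(fit, n_draws = 5,
                                            row_totals = rep(0, 8))
  expect_true(all(pred0 == 0))
  # fully connected graph with equal Dirichlet mass: uniform expected counts
  G1 <- matrix(1L, 6, 6); diag(G1) <- 0L
  fit2 <- fit
  fit2$G_samples <- list(G1)
  fit2$P <- 6
  fit2$row_totals <- rep(600, 6)
  fit2$config$delta1 <- 1
  set.seed(2)
  pred2 <- posterior_predictive_streamlines(fit2, n_draws = 400)
  off <- pred2[row(pred2) != col(pred2)]
  expect_lt(max(abs(off - 120)), 20)    # DM mean 600/5 per off-diagonal cell
})

test_that("degenerate inputs are rejected", {
  expect_error(irm(matrix(0L, 4, 4)), "degenerate")
  expect_error(irm(matrix(1L, 3, 4)), "square")
})
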