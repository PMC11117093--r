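#' Fit the infinite relational model to a streamline-count matrix
#'
#' Step 1 of the two-step pipeline. Places a Chinese restaurant process prior
#' on the partition of ROIs, a collapsed Beta-Bernoulli block prior on the
#' latent binary connectivity graph G, and a Dirichlet compound multinomial
#' likelihood on the rows of the count matrix. The posterior over (Z, G) is
#' explored by MCMC: per iteration one Metropolis sweep over unordered edge
#' flips, one Gibbs sweep over cluster assignments, and one Jain-Neal
#' split-merge proposal. Chains are pooled after burn-in; the graph and
#' coassignment matrix are summarized by their entrywise posterior mode.
#'
#' @param S square nonnegative integer count matrix (a `matrix_table` of kind
#'   `counts` or a plain matrix); the diagonal is a structural zero
#' @param config a [run_config()]; `xi = NULL` resolves to `log(P)`
#' @param g_keep number of thinned graph samples retained per chain for
#'   posterior prediction
#' @param verbose print per-chain progress
#' @return an object of class `irm_fit` with components `partition` (labels,
#'   K, sizes), `G_map`, `M_map`, `rho` (MAP cluster connectivity), posterior
#'   means `G_mean`/`M_mean`, per-chain label samples and log-posterior
#'   traces, and the resolved configuration
#' @export
irm <- function(S, config = run_config(), g_keep = 100, verbose = FALSE) {
  if (inherits(S, "matrix_table")) {
    roi_ids <- S$row_ids
    S <- S$values
  } else {
    S <- as.matrix(S)
    roi_ids <- rownames(S)
  }
  P <- nrow(S)
  if (ncol(S) != P) stop("streamline matrix must be square")
  if (any(S < 0)) stop("streamline counts must be nonnegative")
  if (all(S == 0)) stop("degenerate input: all streamline counts are zero")
  if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_len(P))
  cfg <- config
  if (is.null(cfg$xi)) cfg$xi <- log(P)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  t0 <- proc.time()[["elapsed"]]
  chains <- vector("list", cfg$chains)
  M_mean <- matrix(0, P, P)
  G_mean <- matrix(0, P, P)
  g_samples <- list()
  for (ch in seq_len(cfg$chains)) {
    z0 <- rcrp_partition(P, cfg$xi)
    G0 <- init_graph(S)
    res <- cpp_irm_mcmc(S, G0, z0, cfg$xi, cfg$alpha, cfg$beta,
                        cfg$delta0, cfg$delta1,
                        cfg$iterations, cfg$burnin, cfg$sm_scans,
                        as.integer(g_keep))
    M_mean <- M_mean + res$M_mean
    G_mean <- G_mean + res$G_mean
    g_samples <- c(g_samples, res$G_samples)
    chains[[ch]] <- list(labels = res$labels, log_post = res$log_post,
                         K_trace = res$K_trace, sm_accepts = res$sm_accepts)
    if (verbose)
      message(sprintf("chain %d/%d: K = %d, log posterior = %.1f",
                      ch, cfg$chains,
                      res$K_trace[cfg$iterations],
                      res$log_post[cfg$iterations]))
  }
  M_mean <- M_mean / cfg$chains
  G_mean <- G_mean / cfg$chains
  # entrywise posterior mode; probability exactly 0.5 resolves to 1
  G_map <- (G_mean >= 0.5) * 1L
  diag(G_map) <- 0L
  M_map <- (M_mean >= 0.5) * 1L
  diag(M_map) <- 1L
  part <- decompose_coassignment(M_map)
  rho <- rho_map(G_map, part$labels, cfg$alpha, cfg$beta)

  fit <- structure(list(
    call = match.call(), P = P, roi_ids = roi_ids, config = cfg,
    partition = part, G_map = G_map, M_map = M_map, rho = rho,
    G_mean = G_mean, M_mean = M_mean, chains = chains,
    G_samples = g_samples, row_totals = rowSums(S),
    elapsed = proc.time()[["elapsed"]] - t0), class = "irm_fit")
  fit
}

# draw a partition from the CRP prior (sequential seating)
rcrp_partition <- function(P, xi) {
  z <- integer(P)
  z[1] <- 1L
  K <- 1L
  sizes <- c(1)
  if (P > 1) for (i in 2:P) {
    pr <- c(sizes, xi)
    k <- sample.int(K + 1L, 1L, prob = pr)
    if (k > K) {
      K <- K + 1L
      sizes <- c(sizes, 1)
    } else sizes[k] <- sizes[k] + 1
    z[i] <- k
  }
  z
}

# initial graph: an ROI pair starts as an edge when either directed count
# exceeds the corresponding row's off-diagonal median
init_graph <- function(S) {
  P <- nrow(S)
  med <- vapply(seq_len(P), function(i) median(S[i, -i]), 0)
  G <- (S > med) | t(S > med)
  G <- matrix(as.integer(G), P, P)
  diag(G) <- 0L
  G
}

#' One Metropolis sweep over edge flips
#'
#' Proposes flipping each unordered off-diagonal pair of the graph once,
#' accepting with the ratio of the two affected row likelihoods times the
#' collapsed graph prior. Exposed for diagnostics and validation; [irm()]
#' runs these sweeps internally.
#'
#' @param S count matrix
#' @param G current graph
#' @param labels current partition labels
#' @param config a [run_config()] (xi must be resolved or P-independent)
#' @return list with the updated `G` and the number of accepted flips
#' @export
irm_graph_sweep <- function(S, G, labels, config = run_config(xi = 1)) {
  cfg <- config
  if (is.null(cfg$xi)) cfg$xi <- log(nrow(S))
  cpp_graph_sweep(S, G, as.integer(labels), cfg$xi, cfg$alpha, cfg$beta,
                  cfg$delta0, cfg$delta1)
}

#' One Gibbs sweep over cluster assignments
#'
#' Reassigns each ROI in turn to an existing cluster or a new singleton with
#' probability proportional to the CRP seating rule times the collapsed
#' graph prior; emptied clusters are removed and labels compacted.
#'
#' @inheritParams irm_graph_sweep
#' @return list with the updated `labels`
#' @export
irm_gibbs_sweep <- function(S, G, labels, config = run_config(xi = 1)) {
  cfg <- config
  if (is.null(cfg$xi)) cfg$xi <- log(nrow(S))
  cpp_gibbs_sweep(S, G, as.integer(labels), cfg$xi, cfg$alpha, cfg$beta,
                  cfg$delta0, cfg$delta1)
}

#' One split-merge Metropolis-Hastings proposal
#'
#' Jain-Neal restricted-Gibbs split-merge move on the partition: two anchor
#' ROIs are drawn; co-clustered anchors trigger a split proposal built by
#' restricted Gibbs scans, anchors in different clusters trigger a merge.
#'
#' @inheritParams irm_graph_sweep
#' @return list with the updated `labels` and an acceptance indicator
#' @export
irm_split_merge <- function(S, G, labels, config = run_config(xi = 1)) {
  cfg <- config
  if (is.null(cfg$xi)) cfg$xi <- log(nrow(S))
  cpp_split_merge(S, G, as.integer(labels), cfg$xi, cfg$alpha, cfg$beta,
                  cfg$delta0, cfg$delta1, cfg$sm_scans)
}

#' Entrywise summary of the coassignment posterior
#'
#' Pools retained samples of the coassignment matrix M = ZZ' and returns the
#' entrywise posterior mode (equivalently the posterior mean thresholded at
#' 0.5; an entry at exactly 0.5 resolves to 1) together with the means.
#'
#' @param fit an `irm_fit`, or a list of label matrices (iterations x P)
#' @return list with binary `M_map` and numeric `M_mean`
#' @export
coassignment_map <- function(fit) {
  if (inherits(fit, "irm_fit"))
    return(list(M_map = fit$M_map, M_mean = fit$M_mean))
  labmats <- fit
  if (is.matrix(labmats)) labmats <- list(labmats)
  P <- ncol(labmats[[1]])
  M <- matrix(0, P, P)
  n <- 0L
  for (lm_ in labmats) {
    for (r in seq_len(nrow(lm_))) {
      zz <- lm_[r, ]
      M <- M + outer(zz, zz, "==")
      n <- n + 1L
    }
  }
  if (n == 0L) stop("no retained samples")
  M_mean <- M / n
  M_map <- (M_mean >= 0.5) * 1L
  diag(M_map) <- 1L
  list(M_map = M_map, M_mean = M_mean)
}

#' Decompose a coassignment matrix into a partition
#'
#' Greedy first-seen scan: ROI 1 seeds cluster 1 together with every ROI
#' coassigned with it; each subsequent unassigned ROI joins the cluster of
#' its first already-assigned coassignment partner, or seeds a new cluster
#' with its unassigned partners. When the input is not transitive the scan
#' still yields a partition and a warning reports how many ROI pairs
#' disagree with the final co-membership.
#'
#' @param M symmetric binary matrix with unit diagonal
#' @return list with `labels`, `K`, `sizes`, and `violations` (count of
#'   pairs where `M` disagrees with the returned partition)
#' @export
decompose_coassignment <- function(M) {
  P <- nrow(M)
  stopifnot(ncol(M) == P)
  labels <- integer(P)
  K <- 0L
  for (i in seq_len(P)) {
    if (labels[i] > 0L) next
    partners <- which(M[i, ] == 1)
    assigned <- partners[labels[partners] > 0L]
    if (length(assigned)) {
      labels[i] <- labels[assigned[1]]
    } else {
      K <- K + 1L
      labels[c(i, partners)] <- K
    }
  }
  co <- outer(labels, labels, "==") * 1
  diag(co) <- 1
  viol <- sum((M != co)[upper.tri(M)])
  if (viol > 0)
    warning(sprintf("coassignment matrix is not transitive: %d pair(s) disagree with the decomposed partition", viol))
  list(labels = labels, K = K, sizes = as.integer(table(labels)),
       violations = viol)
}

#' Posterior predictive streamline counts
#'
#' For each draw, picks a retained graph sample and regenerates row-wise
#' Dirichlet compound multinomial counts at the observed row totals,
#' returning the mean predicted matrix.
#'
#' @param fit an `irm_fit`
#' @param n_draws number of predictive draws
#' @param row_totals per-row streamline totals; defaults to the observed ones
#' @return mean predicted count matrix
#' @export
posterior_predictive_streamlines <- function(fit, n_draws = 1000,
                                             row_totals = fit$row_totals) {
  gs <- fit$G_samples
  if (!length(gs)) stop("no retained graph samples")
  P <- fit$P
  d0 <- fit$config$delta0; d1 <- fit$config$delta1
  acc <- matrix(0, P, P)
  for (d in seq_len(n_draws)) {
    G <- gs[[((d - 1L) %% length(gs)) + 1L]]
    acc <- acc + generate_streamlines(G, delta0 = d0, delta1 = d1,
                                      per_row_total = row_totals)
  }
  acc / n_draws
}

# ---- methods ---------------------------------------------------------------

#' @exportS3Method base::print
print.irm_fit <- function(x, ...) {
  cat("Infinite relational model fit\n")
  cat(sprintf("  ROIs: %d   clusters (MAP): %d\n", x$P, x$partition$K))
  cat(sprintf("  cluster sizes: %s\n",
              paste(sort(x$partition$sizes, decreasing = TRUE), collapse = ", ")))
  cat(sprintf("  chains: %d  iterations: %d  burn-in: %d\n",
              x$config$chains, x$config$iterations, x$config$burnin))
  cat(sprintf("  MAP edges: %d of %d pairs\n",
              sum(x$G_map[upper.tri(x$G_map)]), x$P * (x$P - 1) / 2))
  invisible(x)
}

#' @exportS3Method base::summary
summary.irm_fit <- function(object, ...) {
  rho <- object$rho
  out <- list(P = object$P, K = object$partition$K,
              sizes = object$partition$sizes,
              within = diag(rho),
              between = rho[upper.tri(rho)],
              final_log_post = vapply(object$chains,
                                      function(ch) ch$log_post[length(ch$log_post)], 0),
              sm_accepts = vapply(object$chains, function(ch) ch$sm_accepts, 0L),
              elapsed = object$elapsed)
  class(out) <- "summary.irm_fit"
  out
}

#' @exportS3Method base::print
print.summary.irm_fit <- function(x, ...) {
  cat(sprintf("IRM fit: P = %d, K = %d clusters\n", x$P, x$K))
  cat("  within-cluster connectivity: ",
      paste(format(round(sort(x$within, decreasing = TRUE), 3)), collapse = " "), "\n")
  if (length(x$between))
    cat(sprintf("  between-cluster connectivity: median %.3f, max %.3f\n",
                median(x$between), max(x$between)))
  cat(sprintf("  final log posterior per chain: %s\n",
              paste(format(round(x$final_log_post, 1)), collapse = " ")))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}

#' @export
coef.irm_fit <- function(object, ...) object$rho

#' @export
plot.irm_fit <- function(x, what = c("coassignment", "graph", "trace"), ...) {
  what <- match.arg(what)
  if (what == "trace") {
    lp <- x$chains[[1]]$log_post
    plot(lp, type = "l", xlab = "iteration", ylab = "log posterior", ...)
    if (length(x$chains) > 1)
      for (ch in x$chains[-1]) graphics::lines(ch$log_post, col = "grey60")
    return(invisible(x))
  }
  m <- if (what == "coassignment") x$M_mean else x$G_map
  ord <- order(x$partition$labels)
  graphics::image(m[ord, rev(ord)], axes = FALSE, useRaster = TRUE,
                  main = if (what == "coassignment")
                    "posterior coassignment probability" else "MAP graph", ...)
  invisible(x)
}

#' @export
simulate.irm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  gs <- object$G_samples
  if (!length(gs)) stop("no retained graph samples")
  lapply(seq_len(nsim), function(d) {
    G <- gs[[sample.int(length(gs), 1)]]
    generate_streamlines(G, delta0 = object$config$delta0,
                         delta1 = object$config$delta1,
                         per_row_total = object$row_totals)
  })
}
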