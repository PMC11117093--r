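#' Edge confusion rates between a true and an estimated graph
#'
#' Rates over unordered off-diagonal pairs: hit = TP / (TP + FN),
#' correct rejection = TN / (TN + FP), miss = 1 - hit, false alarm = 1 - CR.
#' When the true graph has no non-edges (fully connected truth) CR and FA
#' are undefined and reported as `NA`.
#'
#' @param G_true,G_est symmetric binary adjacency matrices of equal size
#' @return list with `hit`, `miss`, `cr`, `fa` and the raw pair counts
#' @export
edge_confusion <- function(G_true, G_est) {
  if (!all(dim(G_true) == dim(G_est))) stop("dimension mismatch")
  ut <- upper.tri(G_true)
  tv <- G_true[ut]; ev <- G_est[ut]
  tp <- sum(tv == 1 & ev == 1); fn <- sum(tv == 1 & ev == 0)
  tn <- sum(tv == 0 & ev == 0); fp <- sum(tv == 0 & ev == 1)
  hit <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  cr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(hit = hit, miss = 1 - hit, cr = cr, fa = 1 - cr,
       counts = c(tp = tp, fn = fn, tn = tn, fp = fp))
}

#' Match estimated clusters to true clusters
#'
#' Optimal one-to-one assignment maximizing total membership overlap,
#' computed by the Hungarian algorithm on the contingency table of the two
#' partitions. Clusters left over on the larger side are reported as
#' unmatched.
#'
#' @param labels_true,labels_est cluster labelings of the same nodes
#' @return list with a data frame `pairs` (true, est, overlap), and
#'   `unmatched_true` / `unmatched_est`
#' @export
match_clusters <- function(labels_true, labels_est) {
  if (length(labels_true) != length(labels_est)) stop("labelings must cover the same nodes")
  lt <- as.integer(factor(labels_true, levels = unique(labels_true)))
  le <- as.integer(factor(labels_est, levels = unique(labels_est)))
  Kt <- max(lt); Ke <- max(le)
  C <- matrix(0, Kt, Ke)
  for (i in seq_along(lt)) C[lt[i], le[i]] <- C[lt[i], le[i]] + 1
  n <- max(Kt, Ke)
  Cp <- matrix(0, n, n)
  Cp[seq_len(Kt), seq_len(Ke)] <- C
  assign <- solve_assignment(max(Cp) - Cp)     # minimize cost = maximize overlap
  pairs <- data.frame(true = seq_len(n), est = assign)
  pairs$overlap <- Cp[cbind(pairs$true, pairs$est)]
  keep <- pairs$true <= Kt & pairs$est <= Ke
  list(pairs = pairs[keep & pairs$overlap > 0, , drop = FALSE],
       unmatched_true = setdiff(seq_len(Kt), pairs$true[keep & pairs$overlap > 0]),
       unmatched_est = setdiff(seq_len(Ke), pairs$est[keep & pairs$overlap > 0]),
       contingency = C)
}

# Hungarian algorithm (potentials formulation), minimal-cost perfect matching
# on a square cost matrix; returns the column assigned to each row
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  V <- n + 1L                     # virtual start column
  u <- numeric(n); v <- numeric(V)
  p <- integer(V)                 # p[j]: row matched to column j (0 = none)
  way <- integer(V)
  for (i in seq_len(n)) {
    p[V] <- i
    j0 <- V
    minv <- rep(Inf, n)
    used <- rep(FALSE, V)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(V)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == V) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0) ans[p[j]] <- j
  ans
}

#' Recovery of the cluster connectivity matrix
#'
#' Pearson correlation and mean bias between true and estimated
#' cluster-connectivity values over matched cluster pairs (upper triangle
#' plus diagonal).
#'
#' @param rho_true,rho_est cluster connectivity matrices
#' @param matching result of [match_clusters()]
#' @return list with `pearson`, `bias`, and the compared value vectors
#' @export
rho_recovery <- function(rho_true, rho_est, matching) {
  pr <- matching$pairs
  m <- nrow(pr)
  tv <- c(); ev <- c()
  for (a in seq_len(m)) for (b in a:m) {
    tv <- c(tv, rho_true[pr$true[a], pr$true[b]])
    ev <- c(ev, rho_est[pr$est[a], pr$est[b]])
  }
  if (length(tv) < 3)
    return(list(pearson = NA_real_, bias = mean(ev - tv), true = tv, est = ev))
  list(pearson = cor(tv, ev), bias = mean(ev - tv), true = tv, est = ev)
}

#' Recovery of functional factor-model parameters
#'
#' Compares loading, factor-correlation and uniqueness estimates to their
#' generating values after matching and sign-aligning factor columns.
#'
#' @param truth list or `fa_fit` with `loadings`, `phi`, `uniqueness`
#' @param est an `fa_fit`
#' @param matching result of [match_clusters()] on the factor labelings;
#'   `NULL` when columns already correspond
#' @return list of per-block Pearson correlations and mean biases
#' @export
functional_recovery <- function(truth, est, matching = NULL) {
  Lt <- truth$loadings; Le <- est$loadings
  Pt <- truth$phi; Pe <- est$phi
  if (!is.null(matching)) {
    pr <- matching$pairs
    Le <- Le[, pr$est, drop = FALSE]
    Pe <- Pe[pr$est, pr$est, drop = FALSE]
    Lt <- Lt[, pr$true, drop = FALSE]
    Pt <- Pt[pr$true, pr$true, drop = FALSE]
  }
  for (k in seq_len(ncol(Le))) {
    if (sum(Le[, k] * Lt[, k]) < 0) {
      Le[, k] <- -Le[, k]
      Pe[k, ] <- -Pe[k, ]; Pe[, k] <- -Pe[, k]
      diag(Pe) <- 1
    }
  }
  ut <- upper.tri(Pt)
  phi_varies <- sum(ut) >= 3 && sd(Pt[ut]) > 0 && sd(Pe[ut]) > 0
  list(
    loading_pearson = cor(as.vector(Lt), as.vector(Le)),
    loading_bias = mean(Le[Lt != 0] - Lt[Lt != 0]),
    phi_pearson = if (phi_varies) cor(Pt[ut], Pe[ut]) else NA_real_,
    phi_spearman = if (phi_varies) cor(Pt[ut], Pe[ut], method = "spearman") else NA_real_,
    phi_bias = if (any(ut)) mean(Pe[ut] - Pt[ut]) else NA_real_,
    phi_abs_bias = if (any(ut)) mean(abs(Pe[ut]) - abs(Pt[ut])) else NA_real_,
    uniqueness_pearson = cor(truth$uniqueness, est$uniqueness),
    uniqueness_bias = mean(est$uniqueness - truth$uniqueness))
}

#' Run the structural and functional recovery study
#'
#' Drives the full factorial: for each structural condition, generates the
#' ground truth and a streamline-count matrix, fits the relational model and
#' scores edge/cluster/connectivity recovery; then, for each functional
#' condition, generates factor-model data from the data-informed structure
#' and scores EFA and CFA recovery with fit indices. Sizes and sampler
#' settings are configurable so the study can run at reduced scale; the
#' scale used is recorded in the report. Deterministic given `seed`.
#'
#' @param structural character vector of structural condition names
#' @param functional character vector of functional condition names
#' @param cluster_sizes cluster sizes defining P
#' @param config sampler configuration for the structural fits
#' @param n_timepoints functional sample size (defaults to 2P)
#' @param seed master seed
#' @return a `simulation_report` list with `structural` and `functional`
#'   per-condition summaries and a `scale` record
#' @export
run_simulation_study <- function(structural = c("independent", "data_informed",
                                                "random_beta_01", "random_beta_11",
                                                "single"),
                                 functional = c("independent", "random",
                                                "practical1", "practical2",
                                                "practical3"),
                                 cluster_sizes = default_cluster_sizes(),
                                 config = run_config(),
                                 n_timepoints = NULL,
                                 seed = 1) {
  set.seed(seed)
  P <- sum(cluster_sizes)
  if (is.null(n_timepoints)) n_timepoints <- 2 * P
  out_s <- list()
  truth_di <- NULL
  for (sc in structural) {
    res <- tryCatch({
      truth <- make_structural_truth(structural_condition(sc, cluster_sizes))
      if (sc == "data_informed") truth_di <<- truth
      S <- generate_streamlines(truth$G, per_row_total = truth$condition$streamlines_per_row)
      cfg <- config; cfg$seed <- NULL
      fit <- irm(S, cfg)
      conf <- edge_confusion(truth$G, fit$G_map)
      mt <- match_clusters(truth$labels, fit$partition$labels)
      rr <- rho_recovery(truth$rho, fit$rho, mt)
      list(condition = sc, K_true = length(unique(truth$labels)),
           K_est = fit$partition$K, confusion = conf[c("hit", "miss", "cr", "fa")],
           rho_pearson = rr$pearson, rho_bias = rr$bias,
           matched = nrow(mt$pairs))
    }, error = function(e) list(condition = sc, error = conditionMessage(e)))
    out_s[[sc]] <- res
  }
  if (is.null(truth_di))
    truth_di <- make_structural_truth(structural_condition("data_informed", cluster_sizes))
  out_f <- list()
  for (fc in functional) {
    res <- tryCatch({
      lam <- make_loadings(truth_di$labels, truth_di$rho)
      phi <- make_phi(fc, rho = truth_di$rho)
      X <- generate_functional_data(lam, phi, n_timepoints)
      R <- standardize_timeseries(X)$R
      truth_mod <- list(loadings = lam, phi = phi,
                        uniqueness = 1 - diag(lam %*% phi %*% t(lam)))
      efa <- factor_coactivation(R, truth_di$labels, n_timepoints, mode = "efa")
      cfa <- factor_coactivation(R, truth_di$labels, n_timepoints, mode = "cfa")
      list(condition = fc,
           efa = c(functional_recovery(truth_mod, efa),
                   srmr = efa$fit$srmr, rmsea = efa$fit$rmsea),
           cfa = c(functional_recovery(truth_mod, cfa),
                   srmr = cfa$fit$srmr, rmsea = cfa$fit$rmsea))
    }, error = function(e) list(condition = fc, error = conditionMessage(e)))
    out_f[[fc]] <- res
  }
  structure(list(structural = out_s, functional = out_f,
                 scale = list(P = P, cluster_sizes = cluster_sizes,
                              iterations = config$iterations,
                              chains = config$chains, burnin = config$burnin,
                              n_timepoints = n_timepoints, seed = seed)),
            class = "simulation_report")
}

#' @exportS3Method base::print
print.simulation_report <- function(x, ...) {
  cat(sprintf("Simulation study at P = %d (%d iterations, %d chain(s))\n",
              x$scale$P, x$scale$iterations, x$scale$chains))
  for (s in x$structural) {
    if (!is.null(s$error)) {
      cat(sprintf("  %-16s FAILED: %s\n", s$condition, s$error)); next
    }
    cat(sprintf("  %-16s K=%2d (true %2d)  hit=%.3f  cr=%s  rho r=%.3f\n",
                s$condition, s$K_est, s$K_true, s$confusion$hit,
                ifelse(is.na(s$confusion$cr), "--", sprintf("%.3f", s$confusion$cr)),
                s$rho_pearson))
  }
  for (f in x$functional) {
    if (!is.null(f$error)) {
      cat(sprintf("  %-16s FAILED: %s\n", f$condition, f$error)); next
    }
    cat(sprintf("  %-16s EFA srmr=%.3f phi bias=%+.3f | CFA rmsea=%.3f phi bias=%+.3f\n",
                f$condition, f$efa$srmr, f$efa$phi_bias,
                f$cfa$rmsea, f$cfa$phi_bias))
  }
  invisible(x)
}
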