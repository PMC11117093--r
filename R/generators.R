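#' Default cluster sizes for the simulated brain
#'
#' Fourteen clusters of sizes 3, 4, 6, 7, 7, 9, 10, 10, 12, 13, 15, 19, 21,
#' 24, summing to P = 160 ROIs.
#'
#' @return integer vector of cluster sizes
#' @export
default_cluster_sizes <- function() {
  c(3L, 4L, 6L, 7L, 7L, 9L, 10L, 10L, 12L, 13L, 15L, 19L, 21L, 24L)
}

#' Structural simulation condition
#'
#' @param name one of `"data_informed"`, `"independent"`,
#'   `"random_beta_01"`, `"random_beta_11"`, `"single"`
#' @param cluster_sizes integer cluster sizes; for `"single"` a single size
#' @param streamlines_per_row multinomial total per row
#' @return a `structural_condition` list
#' @export
structural_condition <- function(name, cluster_sizes = default_cluster_sizes(),
                                 streamlines_per_row = 5000) {
  name <- match.arg(name, c("data_informed", "independent", "random_beta_01",
                            "random_beta_11", "single"))
  if (name == "single") cluster_sizes <- sum(cluster_sizes)
  structure(list(name = name, P = sum(cluster_sizes),
                 cluster_sizes = as.integer(cluster_sizes),
                 streamlines_per_row = streamlines_per_row),
            class = "structural_condition")
}

#' Generate the structural ground truth for a condition
#'
#' Builds the partition from the condition's cluster sizes, draws the cluster
#' connectivity matrix according to the condition's rule, and samples the
#' binary graph with each unordered ROI pair drawn once as
#' Bernoulli(rho\[z_i, z_j\]) and mirrored.
#'
#' Connectivity rules: `single` uses a single cluster with connectivity 1
#' (graph all ones off-diagonal); `independent` uses a diagonal rho with
#' within-cluster values ~ U(0.6, 1); `random_beta_01` / `random_beta_11`
#' draw every entry iid from Beta(0.1, 0.1) / Beta(1, 1); `data_informed`
#' uses a seeded surrogate mimicking empirically estimated connectivity:
#' strong within-cluster values (~ U(0.75, 0.98)), about 20% strong
#' between-cluster pairs arranged on two hub communities, the rest at noise
#' level, with the correlation form D^-1 rho D^-1 positive definite (see
#' the package vignette for the rationale).
#'
#' @param cond a [structural_condition()] (or a condition name)
#' @param rho optional user-supplied cluster connectivity matrix overriding
#'   the condition rule (e.g., empirically estimated values)
#' @return list with `labels`, `rho`, `G`, and the condition
#' @export
make_structural_truth <- function(cond, rho = NULL) {
  if (is.character(cond)) cond <- structural_condition(cond)
  sizes <- cond$cluster_sizes
  P <- cond$P
  if (sum(sizes) != P) stop("cluster sizes must sum to P")
  labels <- rep(seq_along(sizes), sizes)
  K <- length(sizes)
  if (is.null(rho)) {
    rho <- switch(cond$name,
      single = matrix(1, 1, 1),
      independent = diag(runif(K, 0.6, 1), K),
      random_beta_01 = sym_fill(K, function(n) rbeta(n, 0.1, 0.1)),
      random_beta_11 = sym_fill(K, function(n) rbeta(n, 1, 1)),
      data_informed = data_informed_rho(K))
  } else {
    rho <- as.matrix(rho)
    if (nrow(rho) != K) stop("supplied rho must be K x K")
  }
  G <- matrix(0L, P, P)
  if (cond$name == "single") {
    G[] <- 1L
  } else {
    pu <- rho[cbind(labels[row(G)[upper.tri(G)]], labels[col(G)[upper.tri(G)]])]
    G[upper.tri(G)] <- rbinom(length(pu), 1L, pu)
    G[lower.tri(G)] <- t(G)[lower.tri(G)]
  }
  diag(G) <- 0L
  list(labels = labels, rho = rho, G = G, condition = cond)
}

# Surrogate for an empirically estimated cluster-connectivity matrix.
# Strong within-cluster connectivity (diagonal ~ U(0.75, 0.98)) and roughly
# 20% strong between-cluster pairs, the rest at noise level — but with the
# strong pairs arranged on two latent "hub communities" rather than placed
# independently, as in real connectomes. This structured placement keeps
# D^-1 rho D^-1 positive definite, which real estimated matrices satisfy
# and which the correlation-form functional conditions require.
data_informed_rho <- function(K, max_retries = 1000) {
  for (t in seq_len(max_retries)) {
    d <- runif(K, 0.75, 0.98)
    v <- matrix(0, K, 2)
    nh <- min(K, max(2, round(0.64 * K)))
    hubs <- sample.int(K, nh)
    grp <- rep(1:2, length.out = nh)
    v[cbind(hubs, grp)] <- runif(nh, 0.75, 0.85)
    others <- setdiff(seq_len(K), hubs)
    if (length(others))
      v[cbind(others, sample(1:2, length(others), replace = TRUE))] <-
        runif(length(others), 0.05, 0.15)
    C <- tcrossprod(v)
    diag(C) <- 1
    small <- abs(C) < 0.3 & upper.tri(C)
    C[small] <- C[small] + runif(sum(small), 0, 0.05)
    C[lower.tri(C)] <- t(C)[lower.tri(C)]
    if (!is_pd(C, tol = 0.02)) next
    D <- diag(sqrt(d), K)
    return(D %*% C %*% D)
  }
  stop("could not construct a positive-definite data-informed surrogate")
}

sym_fill <- function(K, rfun) {
  r <- matrix(0, K, K)
  diag(r) <- rfun(K)
  off <- rfun(K * (K - 1) / 2)
  r[upper.tri(r)] <- off
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  r
}

#' Sample a streamline-count matrix given a graph
#'
#' Row-wise Dirichlet compound multinomial sampling: for each row, a
#' probability vector over the off-diagonal cells is drawn from
#' Dirichlet(delta1 g_i + delta0 (1 - g_i)) and counts from a multinomial at
#' the requested total. The diagonal is a structural zero.
#'
#' @param G symmetric binary adjacency, zero diagonal
#' @param delta0,delta1 Dirichlet mass for absent/present edges
#' @param per_row_total scalar or per-row vector of totals
#' @return integer count matrix
#' @export
generate_streamlines <- function(G, delta0 = 0.1, delta1 = 1,
                                 per_row_total = 5000) {
  P <- nrow(G)
  tot <- rep_len(per_row_total, P)
  S <- matrix(0, P, P)
  for (i in seq_len(P)) {
    if (tot[i] <= 0) next
    b <- ifelse(G[i, -i] == 1, delta1, delta0)
    y <- rgamma(P - 1, shape = b)
    y <- y / sum(y)
    S[i, -i] <- rmultinom(1, tot[i], y)
  }
  storage.mode(S) <- "integer"
  S
}

#' Cluster-pattern factor loadings
#'
#' Each ROI loads only on its own cluster's factor; the loading is drawn from
#' Normal(rho_aa, rho_aa / 10) where rho_aa is the within-cluster
#' connectivity. Draws are resampled into (0, `max_loading`] so that the
#' implied uniqueness 1 - lambda^2 stays positive.
#'
#' @param labels cluster labels
#' @param rho cluster connectivity matrix (diagonal used)
#' @param max_loading upper truncation for loadings
#' @return P x K loading matrix with zero cross-loadings
#' @export
make_loadings <- function(labels, rho, max_loading = 0.95) {
  K <- nrow(rho)
  P <- length(labels)
  L <- matrix(0, P, K)
  for (i in seq_len(P)) {
    a <- labels[i]
    repeat {
      l <- rnorm(1, rho[a, a], rho[a, a] / 10)
      if (l > 0 && l <= max_loading) break
    }
    L[i, a] <- l
  }
  L
}

#' Factor correlation matrix for a functional condition
#'
#' Five generation rules: `independent` returns the identity;
#' `random` draws off-diagonals from a truncated normal
#' TN(0, 0.25, \[-0.6, 0.6\]); `practical1` rescales the structural
#' connectivity rho to correlation form (D^-1 rho D^-1 with D the square
#' roots of its diagonal), jitters the diagonal with N(0.005, 0.05) draws and
#' renormalizes until positive definite; `practical2` maps strong structural
#' connections (rho_ab > 0.3) to weak coactivation values
#' N(1 - rho_ab, rho_ab / 10) and noise-level connections to N(0, 0.05);
#' `practical3` maps noise-level connections to TN(0.3, 0.3, \[0.1, 0.6\])
#' and strong ones to N(0, 0.05). All outputs are symmetric, unit-diagonal,
#' positive definite. Definiteness is enforced by rejection, except for
#' `practical3`, where the drawn entry pattern (most of the matrix near
#' 0.3) is structurally indefinite at realistic K; there the draw is
#' repaired by clipping eigenvalues at a small positive floor and
#' renormalizing to correlation form, which preserves the inverted
#' structure while attenuating magnitudes (see the vignette).
#'
#' @param name condition name: `"independent"`, `"random"`, `"practical1"`,
#'   `"practical2"`, `"practical3"`
#' @param rho structural cluster connectivity (required for practical
#'   conditions, and sets K otherwise)
#' @param K number of factors when `rho` is not supplied
#' @param max_retries positive-definiteness rejection cap
#' @return K x K factor correlation matrix
#' @export
make_phi <- function(name, rho = NULL, K = if (!is.null(rho)) nrow(rho) else 14,
                     max_retries = 10000) {
  name <- match.arg(name, c("independent", "random", "practical1",
                            "practical2", "practical3"))
  if (name == "independent") return(diag(K))
  if (name == "random") {
    for (t in seq_len(max_retries)) {
      phi <- diag(K)
      off <- rtruncnorm(K * (K - 1) / 2, 0, 0.25, -0.6, 0.6)
      phi[upper.tri(phi)] <- off
      phi[lower.tri(phi)] <- t(phi)[lower.tri(phi)]
      if (is_pd(phi)) return(phi)
    }
    stop("make_phi: could not draw a positive-definite random correlation matrix after ", max_retries, " tries")
  }
  if (is.null(rho)) stop("practical conditions require the structural rho")
  K <- nrow(rho)
  if (name == "practical1") {
    D <- diag(1 / sqrt(diag(rho)), K)
    phi_star <- D %*% rho %*% D
    for (t in seq_len(max_retries)) {
      m <- phi_star
      diag(m) <- diag(m) + rnorm(K, 0.005, 0.05)
      if (any(diag(m) <= 0)) next
      phi <- cov2cor(m)
      if (is_pd(phi)) return(phi)
    }
    stop("make_phi: practical1 construction not positive definite after ", max_retries, " tries")
  }
  big <- rho > 0.3
  draw <- function() {
    phi <- diag(K)
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      v <- if (name == "practical2") {
        if (big[a, b]) rnorm(1, 1 - rho[a, b], rho[a, b] / 10) else rnorm(1, 0, 0.05)
      } else {
        if (big[a, b]) rnorm(1, 0, 0.05) else rtruncnorm(1, 0.3, 0.3, 0.1, 0.6)
      }
      phi[a, b] <- phi[b, a] <- v
    }
    phi
  }
  if (name == "practical3") return(pd_repair(draw()))
  for (t in seq_len(max_retries)) {
    phi <- draw()
    if (max(abs(phi[upper.tri(phi)])) < 1 && is_pd(phi)) return(phi)
  }
  stop("make_phi: ", name, " construction not positive definite after ", max_retries, " tries")
}

# clip eigenvalues at a positive floor and renormalize to a correlation
# matrix; used where a drawn entry pattern is structurally indefinite
pd_repair <- function(m, floor = 0.05) {
  e <- eigen(m, symmetric = TRUE)
  out <- e$vectors %*% diag(pmax(e$values, floor)) %*% t(e$vectors)
  cov2cor(out)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

is_pd <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol
}

#' Generate functional time series from a factor model
#'
#' Assembles the model-implied correlation matrix Sigma = Lambda Phi Lambda'
#' + Psi with Psi = 1 - diag(Lambda Phi Lambda') (unit diagonal) and draws N
#' iid multivariate normal rows.
#'
#' @param loadings P x K loading matrix
#' @param phi K x K factor correlation matrix
#' @param n_timepoints number of rows to draw
#' @return N x P matrix of functional observations
#' @export
generate_functional_data <- function(loadings, phi, n_timepoints) {
  common <- loadings %*% phi %*% t(loadings)
  psi <- 1 - diag(common)
  if (any(psi <= 0))
    stop("communality >= 1 for some ROI; uniqueness would be nonpositive")
  sigma <- common + diag(psi)
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("implied correlation matrix is not positive definite"))
  P <- nrow(sigma)
  matrix(rnorm(n_timepoints * P), n_timepoints, P) %*% ch
}
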