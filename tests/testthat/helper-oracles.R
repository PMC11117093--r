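# Independent oracles for the samplers and densities: brute-force
# enumeration of set partitions and graphs, and exhaustive evaluation of the
# joint posterior over (partition, graph) on tiny problems.

# all set partitions of n items, as label vectors (first-appearance coding)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    K <- max(p)
    for (k in seq_len(K + 1)) out[[length(out) + 1]] <- c(p, k)
  }
  out
}

# all symmetric binary graphs on n nodes (zero diagonal)
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    G <- matrix(0L, n, n)
    G[upper.tri(G)] <- bits
    G[lower.tri(G)] <- t(G)[lower.tri(G)]
    G
  })
}

# unnormalized log joint posterior of (labels, G) given counts S
log_joint <- function(S, G, labels, xi, alpha = 1, beta = 1,
                      delta0 = 0.1, delta1 = 1) {
  P <- nrow(S)
  ll <- 0
  for (i in seq_len(P))
    ll <- ll + dm_row_log_likelihood(S[i, -i], G[i, -i], delta0, delta1)
  ll + graph_log_prior(G, labels, alpha, beta) + crp_log_pmf(labels, xi)
}

# exhaustive posterior over (partition, graph): returns normalized weights
# plus marginal edge / coassignment probabilities and P(K = k)
enumerate_posterior <- function(S, xi, alpha = 1, beta = 1,
                                delta0 = 0.1, delta1 = 1) {
  P <- nrow(S)
  parts <- all_partitions(P)
  graphs <- all_graphs(P)
  lw <- matrix(NA_real_, length(parts), length(graphs))
  for (a in seq_along(parts))
    for (b in seq_along(graphs))
      lw[a, b] <- log_joint(S, graphs[[b]], parts[[a]], xi, alpha, beta,
                            delta0, delta1)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  edge <- matrix(0, P, P)
  coas <- matrix(0, P, P)
  pk <- numeric(P)
  for (a in seq_along(parts)) {
    co <- outer(parts[[a]], parts[[a]], "==") * 1
    wa <- sum(w[a, ])
    coas <- coas + wa * co
    pk[max(parts[[a]])] <- pk[max(parts[[a]])] + wa
  }
  for (b in seq_along(graphs)) edge <- edge + sum(w[, b]) * graphs[[b]]
  list(weights = w, parts = parts, graphs = graphs,
       edge_marginal = edge, coassign_marginal = coas, pK = pk)
}

# marginal posterior over partitions only, for a fixed graph
enumerate_partition_posterior <- function(G, xi, alpha = 1, beta = 1) {
  parts <- all_partitions(nrow(G))
  lw <- vapply(parts, function(p)
    graph_log_prior(G, p, alpha, beta) + crp_log_pmf(p, xi), 0)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  P <- nrow(G)
  coas <- matrix(0, P, P)
  pk <- numeric(P)
  for (a in seq_along(parts)) {
    coas <- coas + w[a] * (outer(parts[[a]], parts[[a]], "==") * 1)
    pk[max(parts[[a]])] <- pk[max(parts[[a]])] + w[a]
  }
  list(parts = parts, w = w, coassign_marginal = coas, pK = pk)
}

# batch-means Monte Carlo standard error of the mean of a 0/1 (or numeric)
# chain; conservative for autocorrelated samplers
mc_se <- function(x, n_batch = 40) {
  n <- length(x)
  b <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(k) mean(x[((k - 1) * b + 1):(k * b)]), 0)
  sd(means) / sqrt(n_batch)
}

# all count vectors of length p with a fixed total
all_count_vectors <- function(p, total) {
  if (p == 1) return(list(total))
  out <- list()
  for (k in 0:total)
    for (rest in all_count_vectors(p - 1, total - k))
      out[[length(out) + 1]] <- c(k, rest)
  out
}

rand_corr <- function(P, strength = 3) {
  A <- matrix(rnorm(P * P), P)
  cov2cor(crossprod(A) + diag(strength, P))
}

# all permutations of 1..n as rows (tiny n only)
perm_rows <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perm_rows(n - 1)
  out <- NULL
  for (k in seq_len(n)) out <- rbind(out, cbind(k, sub + (sub >= k)))
  out
}

make_fa_fit <- function(...) irmfa:::new_fa_fit(converged = TRUE, ...)
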