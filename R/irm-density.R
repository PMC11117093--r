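#' Log pmf of the Chinese restaurant process
#'
#' Probability of a partition of P items under the CRP with concentration
#' `xi`: \eqn{K \log\xi + \log\Gamma(\xi) - \log\Gamma(\xi + P) +
#' \sum_a \log\Gamma(n_a)}. Normalized over all set partitions.
#'
#' @param labels integer cluster labels (any coding; only the induced
#'   partition matters)
#' @param xi concentration parameter, > 0
#' @return log probability
#' @export
crp_log_pmf <- function(labels, xi) {
  if (length(labels) == 0L) stop("empty partition")
  if (xi <= 0) stop("xi must be > 0")
  n_a <- as.numeric(table(labels))
  K <- length(n_a)
  P <- length(labels)
  K * log(xi) + lgamma(xi) - lgamma(xi + P) + sum(lgamma(n_a))
}

#' Log likelihood of one streamline-count row
#'
#' Dirichlet compound multinomial log pmf for a row of off-diagonal counts,
#' with per-cell Dirichlet mass `delta1` on edges and `delta0` on non-edges.
#' The diagonal cell is a structural zero and is excluded by the caller.
#'
#' @param counts nonnegative integer counts (one row, diagonal removed)
#' @param edges binary edge indicators of the same length
#' @param delta0,delta1 Dirichlet parameters for absent/present edges
#' @return log probability of the count vector given its total
#' @export
dm_row_log_likelihood <- function(counts, edges, delta0, delta1) {
  if (length(counts) != length(edges)) stop("counts and edges must have equal length")
  if (any(counts < 0)) stop("negative counts")
  if (length(counts) == 0L) return(0)
  b <- ifelse(edges == 1, delta1, delta0)
  Tn <- sum(counts)
  Bn <- sum(b)
  lgamma(Tn + 1) - sum(lgamma(counts + 1)) +
    lgamma(Bn) - lgamma(Bn + Tn) +
    sum(lgamma(b + counts) - lgamma(b))
}

#' Collapsed log prior of an edge graph given a partition
#'
#' Marginal probability of the binary graph with block edge probabilities
#' integrated out under Beta(alpha, beta): a product of Beta-function ratios
#' over unordered cluster pairs, each undirected ROI pair counted once.
#'
#' @param G symmetric binary adjacency matrix, zero diagonal
#' @param labels cluster labels of the nodes
#' @param alpha,beta Beta prior parameters, > 0
#' @return log prior probability of `G`
#' @export
graph_log_prior <- function(G, labels, alpha, beta) {
  t <- pair_tallies(G, labels)
  K <- nrow(t$M_plus)
  s <- 0
  for (a in seq_len(K))
    for (b in a:K)
      s <- s + lbeta(alpha + t$M_plus[a, b], beta + t$M_minus[a, b]) -
        lbeta(alpha, beta)
  s
}

#' Edge and non-edge tallies per cluster pair
#'
#' @param G symmetric binary adjacency, zero diagonal
#' @param labels cluster labels
#' @return list with symmetric `M_plus`, `M_minus` matrices (unordered node
#'   pairs counted once) and the compacted labels
#' @export
pair_tallies <- function(G, labels) {
  labs <- as.integer(factor(labels, levels = unique(labels)))
  K <- max(labs)
  Mp <- matrix(0, K, K); Mm <- matrix(0, K, K)
  P <- nrow(G)
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      a <- labs[i]; b <- labs[j]
      e <- G[i, j]
      Mp[a, b] <- Mp[a, b] + e
      Mm[a, b] <- Mm[a, b] + 1 - e
      if (a != b) {
        Mp[b, a] <- Mp[b, a] + e
        Mm[b, a] <- Mm[b, a] + 1 - e
      }
    }
  }
  list(M_plus = Mp, M_minus = Mm, labels = labs)
}

#' MAP cluster-connectivity matrix
#'
#' Collapsed posterior mode of the block edge probabilities:
#' \eqn{(M_+ + \alpha) / (M_+ + M_- + \alpha + \beta)} per unordered cluster
#' pair; within-cluster denominators count the \eqn{n_a(n_a-1)/2} possible
#' edges.
#'
#' @param G symmetric binary adjacency, zero diagonal
#' @param labels cluster labels
#' @param alpha,beta Beta prior parameters
#' @return K x K symmetric matrix of probabilities
#' @export
rho_map <- function(G, labels, alpha = 1, beta = 1) {
  t <- pair_tallies(G, labels)
  (t$M_plus + alpha) / (t$M_plus + t$M_minus + alpha + beta)
}
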