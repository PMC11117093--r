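#' Standardize a functional time-series matrix
#'
#' Centers and scales each column to mean 0, variance 1, and returns the
#' sample correlation matrix R = X'X / (N - 1).
#'
#' @param X N x P numeric matrix, N >= 2
#' @return list with the standardized matrix `X` and correlation matrix `R`
#' @export
standardize_timeseries <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two time points")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant column: ", paste(which(sds == 0), collapse = ", "))
  Xs <- scale(X)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  R <- crossprod(Xs) / (nrow(X) - 1)
  diag(R) <- 1
  list(X = Xs, R = R)
}

#' Ridge-regularize a correlation matrix
#'
#' Adds `epsilon` to the diagonal and converts back to correlation form,
#' which scales every off-diagonal entry by 1 / (1 + epsilon) and shifts all
#' eigenvalues by epsilon before rescaling. The output is positive definite
#' whenever epsilon exceeds the magnitude of the smallest eigenvalue.
#'
#' @param R symmetric unit-diagonal matrix
#' @param epsilon nonnegative ridge
#' @return regularized correlation matrix; attribute `"pd"` reports
#'   definiteness (a warning is raised when still non-PD)
#' @export
regularize_correlation <- function(R, epsilon = 0.01) {
  stopifnot(epsilon >= 0)
  out <- R / (1 + epsilon)
  diag(out) <- 1
  pd <- is_pd(out)
  if (!pd) warning("matrix is still not positive definite after regularization")
  attr(out, "pd") <- pd
  out
}

#' Model-implied correlation matrix
#'
#' @param model an `fa_fit`, or a loading matrix (then `phi` and
#'   `uniqueness` must be given)
#' @param phi factor correlation matrix
#' @param uniqueness per-variable unique variances
#' @return Lambda Phi Lambda' + Psi
#' @export
implied_sigma <- function(model, phi = NULL, uniqueness = NULL) {
  if (inherits(model, "fa_fit")) {
    L <- model$loadings; phi <- model$phi; uniqueness <- model$uniqueness
  } else L <- as.matrix(model)
  s <- L %*% phi %*% t(L) + diag(uniqueness, nrow(L))
  (s + t(s)) / 2
}

#' Maximum-likelihood factor extraction
#'
#' Fits the exploratory factor model with uncorrelated factors (Phi = I) by
#' maximum likelihood, returning the unrotated loadings and uniquenesses.
#' Extraction is delegated to [stats::factanal()]; nonconvergence and
#' Heywood cases (uniqueness at its lower bound) are flagged on the result,
#' not raised as errors.
#'
#' @param R positive-definite correlation matrix
#' @param K number of factors, K < P
#' @param n sample size behind `R`
#' @param lower lower bound for uniquenesses during optimization
#' @return an `fa_fit` with `mode = "efa"` (unrotated: `phi` is the
#'   identity)
#' @export
fit_efa <- function(R, K, n, lower = 0.005) {
  P <- nrow(R)
  stopifnot(K < P)
  fa <- tryCatch(
    factanal(covmat = R, factors = K, n.obs = n, rotation = "none",
             control = list(lower = lower, nstart = 1,
                            opt = list(maxit = 2000))),
    error = function(e) e)
  if (inherits(fa, "error")) {
    return(new_fa_fit(loadings = matrix(0, P, K), phi = diag(K),
                      uniqueness = rep(1, P), mode = "efa", R = R, n = n,
                      converged = FALSE,
                      warnings = paste("extraction failed:", conditionMessage(fa))))
  }
  L <- matrix(fa$loadings, P, K)
  psi <- fa$uniquenesses
  warn <- character(0)
  if (any(psi <= lower + 1e-6)) warn <- c(warn, "Heywood")
  new_fa_fit(loadings = L, phi = diag(K), uniqueness = psi, mode = "efa",
             R = R, n = n, converged = fa$converged %||% TRUE, warnings = warn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Oblique target rotation by gradient projection
#'
#' Rotates an unrotated loading matrix toward a target matrix B by
#' minimizing the partially specified target criterion
#' f(Lambda) = sum over specified cells of (lambda_ij - b_ij)^2 over
#' oblique rotations (Lambda = Lambda0 (T')^-1 with unit-length columns of
#' T), using gradient projection with step halving. For a binary cluster
#' pattern the specified cells default to the zero cells — the rotation
#' drives cross-loadings toward zero and leaves the magnitude of the
#' in-cluster loadings to the data, which is what keeps the solution free
#' of spurious factor correlation. Supplying `weights` overrides this
#' (weights of 1 everywhere give the fully specified criterion). The
#' criterion is non-increasing across iterations by construction. Multiple
#' starts are used (identity plus random) and the best criterion wins; ties
#' resolve to the identity start. Columns of the solution are permuted and
#' sign-aligned to best match the target.
#'
#' @param model an `fa_fit` from [fit_efa()] (or a loading matrix)
#' @param target P x K target matrix (typically the binary cluster pattern)
#' @param weights P x K matrix of cell weights; default: zero cells of a
#'   binary target are specified (weight 1), nonzero cells unspecified
#'   (weight 0); for a non-binary target all cells are specified
#' @param n_starts number of random starts added to the identity start
#' @param maxit,tol gradient-projection controls
#' @return an `fa_fit` with rotated `loadings`, factor correlation `phi`,
#'   the criterion value `criterion` and rotation matrix `rotation`
#' @export
target_rotate <- function(model, target, weights = NULL, n_starts = 10,
                          maxit = 2000, tol = 1e-6) {
  if (inherits(model, "fa_fit")) {
    L0 <- model$loadings; psi <- model$uniqueness
  } else {
    L0 <- as.matrix(model); psi <- NULL
  }
  target <- as.matrix(target)
  K <- ncol(L0)
  stopifnot(ncol(target) == K, nrow(target) == nrow(L0))
  if (is.null(weights)) {
    weights <- if (all(target %in% c(0, 1))) (target == 0) * 1 else
      matrix(1, nrow(target), ncol(target))
  }
  stopifnot(all(dim(weights) == dim(target)))
  best <- NULL
  starts <- c(list(diag(K)), lapply(seq_len(n_starts), function(s) {
    Tm <- matrix(rnorm(K * K), K, K)
    sweep(Tm, 2, sqrt(colSums(Tm^2)), "/")
  }))
  for (Tm in starts) {
    res <- gp_oblq(L0, target, weights, Tm, maxit = maxit, tol = tol)
    if (is.null(best) || res$f < best$f - 1e-12) best <- res
  }
  al <- align_columns(best$L, best$Phi, target)
  out <- if (inherits(model, "fa_fit")) model else
    new_fa_fit(loadings = al$L, phi = al$Phi, uniqueness = rep(NA_real_, nrow(L0)),
               mode = "efa", R = NULL, n = NA_integer_, converged = best$converged,
               warnings = character(0))
  out$loadings <- al$L
  out$phi <- al$Phi
  if (!is.null(psi)) out$uniqueness <- psi
  out$criterion <- best$f
  out$rotation <- best$Tmat
  out$converged <- isTRUE(out$converged) && best$converged
  if (!best$converged) out$warnings <- c(out$warnings, "rotation not converged")
  out
}

# gradient projection for oblique rotation, weighted least-squares target
# criterion over the specified cells
gp_oblq <- function(A, B, W, Tmat, maxit = 2000, tol = 1e-6) {
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  f <- sum(W * (L - B)^2)
  G <- -t(t(L) %*% (2 * W * (L - B)) %*% Ti)
  al <- 1
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    improved <- FALSE
    for (half in 0:25) {
      X <- Tmat - al * Gp
      Tt <- sweep(X, 2, sqrt(colSums(X^2)), "/")
      Tti <- tryCatch(solve(Tt), error = function(e) NULL)
      if (!is.null(Tti)) {
        Lt <- A %*% t(Tti)
        ft <- sum(W * (Lt - B)^2)
        if (ft < f - 0.5 * s^2 * al) { improved <- TRUE; break }
      } else ft <- Inf
      al <- al / 2
    }
    if (!improved) { converged <- TRUE; break }  # criterion at numerical floor
    if (ft > f + 1e-10)
      stop("target rotation: criterion failed to decrease")
    Tmat <- Tt; L <- Lt; f <- ft; Ti <- Tti
    G <- -t(t(L) %*% (2 * W * (L - B)) %*% Ti)
  }
  list(L = L, Phi = t(Tmat) %*% Tmat, Tmat = Tmat, f = f, converged = converged)
}

# permute columns by greedy maximum absolute congruence with the target,
# then flip signs so each column's dominant target block is positive
align_columns <- function(L, Phi, target) {
  K <- ncol(L)
  cong <- abs(crossprod(L, target))          # est cols x target cols
  perm <- integer(K)
  used <- rep(FALSE, K)
  for (k in order(-apply(cong, 2, max))) {
    cand <- order(-cong[, k])
    cand <- cand[!used[cand]][1]
    perm[k] <- cand
    used[cand] <- TRUE
  }
  L <- L[, perm, drop = FALSE]
  Phi <- Phi[perm, perm, drop = FALSE]
  for (k in seq_len(K)) {
    blk <- target[, k] != 0
    if (any(blk) && sum(L[blk, k]) < 0) {
      L[, k] <- -L[, k]
      Phi[k, ] <- -Phi[k, ]
      Phi[, k] <- -Phi[, k]
    }
  }
  list(L = L, Phi = Phi)
}

#' Confirmatory factor analysis with fixed zero cross-loadings
#'
#' Maximum-likelihood estimation of the factor model in which each ROI loads
#' only on its own cluster's factor (all cross-loadings fixed to 0), the
#' factor correlation matrix is kept positive definite through a
#' unit-row-norm Cholesky parameterization, and uniquenesses are bounded
#' below by `psi_floor`. Estimation pathologies (nonconvergence, Heywood
#' cases, near-singular factor correlations) are flagged on the returned
#' object rather than raised.
#'
#' @param R positive-definite correlation matrix
#' @param pattern P x K binary pattern with exactly one 1 per row, or a
#'   vector of cluster labels
#' @param n sample size behind `R`
#' @param psi_floor lower bound for uniquenesses
#' @param maxit optimizer iteration cap
#' @return an `fa_fit` with `mode = "cfa"`
#' @export
fit_cfa <- function(R, pattern, n, psi_floor = 1e-3, maxit = 2000) {
  if (is.matrix(pattern)) {
    stopifnot(all(rowSums(pattern != 0) == 1))
    block <- max.col(pattern != 0)
  } else block <- as.integer(factor(pattern))
  P <- nrow(R)
  K <- max(block)
  stopifnot(length(block) == P)
  ldR <- as.numeric(determinant(R, logarithm = TRUE)$modulus)
  nw <- K * (K - 1) / 2

  build_W <- function(uu) {
    W <- diag(K)
    if (nw) W[upper.tri(W)] <- 0
    idx <- 1L
    for (i in seq_len(K)) {
      if (i > 1) {
        W[i, seq_len(i - 1)] <- uu[idx:(idx + i - 2L)]
        idx <- idx + i - 1L
      }
      W[i, ] <- W[i, ] / sqrt(sum(W[i, ]^2))
    }
    W
  }

  objgrad <- function(theta, want_grad = TRUE) {
    lam <- theta[seq_len(P)]
    uu <- if (nw) theta[P + seq_len(nw)] else numeric(0)
    lpsi <- theta[P + nw + seq_len(P)]
    psi <- psi_floor + exp(lpsi)
    W <- build_W(uu)
    Phi <- W %*% t(W)
    Sig <- (lam %o% lam) * Phi[block, block]
    diag(Sig) <- diag(Sig) + psi
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(list(f = 1e10, g = NULL))
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    f <- logdet + sum(Sinv * R) - ldR - P
    if (!want_grad) return(list(f = f))
    Om <- Sinv - Sinv %*% R %*% Sinv          # dF/dSigma
    Lam <- matrix(0, P, K)
    Lam[cbind(seq_len(P), block)] <- lam
    OLP <- Om %*% Lam %*% Phi
    g_lam <- 2 * OLP[cbind(seq_len(P), block)]
    g_uu <- numeric(nw)
    if (nw) {
      M <- crossprod(Lam, Om %*% Lam)
      dW <- 2 * M %*% W
      # chain through the row normalization w_i = v_i / |v_i|
      idx <- 1L
      for (i in 2:K) {
        v <- c(uu[idx:(idx + i - 2L)], 1)
        nv <- sqrt(sum(v^2))
        w <- v / nv
        dv <- (dW[i, seq_len(i)] - sum(dW[i, seq_len(i)] * w) * w) / nv
        g_uu[idx:(idx + i - 2L)] <- dv[seq_len(i - 1L)]
        idx <- idx + i - 1L
      }
    }
    g_psi <- diag(Om) * (psi - psi_floor)
    list(f = f, g = c(g_lam, g_uu, g_psi))
  }

  lam0 <- vapply(seq_len(P), function(i) {
    mates <- setdiff(which(block == block[i]), i)
    m <- if (length(mates)) mean(R[i, mates]) else 0.25
    sqrt(min(max(m, 0.04), 0.9))
  }, 0)
  psi0 <- pmax(1 - lam0^2, 0.05)
  theta <- c(lam0, rep(0, nw), log(psi0 - psi_floor))

  opt <- optim(theta,
               fn = function(th) objgrad(th, want_grad = FALSE)$f,
               gr = function(th) objgrad(th)$g,
               method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e4))
  th <- opt$par
  lam <- th[seq_len(P)]
  W <- build_W(if (nw) th[P + seq_len(nw)] else numeric(0))
  Phi <- W %*% t(W)
  psi <- psi_floor + exp(th[P + nw + seq_len(P)])
  # sign convention: factors oriented so most loadings are positive
  for (k in seq_len(K)) {
    if (sum(lam[block == k]) < 0) {
      lam[block == k] <- -lam[block == k]
      Phi[k, ] <- -Phi[k, ]; Phi[, k] <- -Phi[, k]
      diag(Phi) <- 1
    }
  }
  Lam <- matrix(0, P, K)
  Lam[cbind(seq_len(P), block)] <- lam
  warn <- character(0)
  if (opt$convergence != 0) warn <- c(warn, "nonconvergence")
  if (any(psi <= psi_floor + 1e-5)) warn <- c(warn, "Heywood")
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) warn <- c(warn, "factor correlation matrix near-singular")
  new_fa_fit(loadings = Lam, phi = Phi, uniqueness = psi, mode = "cfa",
             R = R, n = n, converged = opt$convergence == 0,
             warnings = warn, discrepancy = opt$value, pattern_block = block)
}

new_fa_fit <- function(loadings, phi, uniqueness, mode, R, n, converged,
                       warnings = character(0), discrepancy = NULL,
                       pattern_block = NULL) {
  structure(list(loadings = loadings, phi = phi, uniqueness = uniqueness,
                 mode = mode, R = R, n = n, converged = converged,
                 warnings = warnings, discrepancy = discrepancy,
                 pattern_block = pattern_block),
            class = "fa_fit")
}

#' Absolute fit indices for a factor model
#'
#' SRMR is the root mean square of residual correlations; for EFA solutions
#' (uniquenesses tied to 1 - communality on a correlation metric) it is
#' computed over off-diagonal elements only, for CFA (free uniquenesses) the
#' diagonal is included — the choice is recorded in the output. RMSEA is
#' sqrt(max(chisq - df, 0) / (df (n - 1))) with chisq = (n - 1) F_ML.
#' Degrees of freedom: EFA ((P-K)^2 - (P+K)) / 2; CFA
#' P(P+1)/2 - (P free loadings + K(K-1)/2 + P uniquenesses).
#'
#' @param R sample correlation matrix
#' @param model an `fa_fit`
#' @param n sample size
#' @return list of class `fa_fit_indices`: `srmr`, `rmsea`, `chisq`,
#'   `discrepancy` (F_ML), `df`, `n`, `srmr_elements`
#' @export
fit_indices <- function(R, model, n = model$n) {
  sigma <- implied_sigma(model)
  resid <- R - sigma
  P <- nrow(R)
  K <- ncol(model$loadings)
  if (model$mode == "cfa") {
    sel <- upper.tri(resid, diag = TRUE)
    df <- P * (P + 1) / 2 - (P + K * (K - 1) / 2 + P)
    elements <- "including diagonal"
  } else {
    sel <- upper.tri(resid)
    df <- ((P - K)^2 - (P + K)) / 2
    elements <- "off-diagonal only"
  }
  srmr <- sqrt(mean(resid[sel]^2))
  fml <- ml_discrepancy(R, sigma)
  chisq <- (n - 1) * fml
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n - 1))) else NA_real_
  structure(list(srmr = srmr, rmsea = rmsea, chisq = chisq,
                 discrepancy = fml, df = df, n = n,
                 srmr_elements = elements,
                 flagged = df <= 0), class = "fa_fit_indices")
}

ml_discrepancy <- function(R, sigma) {
  ch <- chol(sigma)
  logdet <- 2 * sum(log(diag(ch)))
  ldR <- as.numeric(determinant(R, logarithm = TRUE)$modulus)
  logdet + sum(chol2inv(ch) * R) - ldR - nrow(R)
}

#' @exportS3Method base::print
print.fa_fit_indices <- function(x, ...) {
  cat(sprintf("SRMR = %.4f (%s)  RMSEA = %.4f  chisq = %.1f on df = %d (n = %d)\n",
              x$srmr, x$srmr_elements, x$rmsea, x$chisq, x$df, x$n))
  invisible(x)
}

#' Fit a structurally constrained factor model
#'
#' Step 2 of the pipeline: fits either the exploratory model (maximum
#' likelihood extraction followed by oblique target rotation toward the
#' cluster pattern) or the confirmatory model (cross-loadings fixed to
#' zero), with the structural partition defining the factors, and computes
#' absolute fit indices.
#'
#' @param R correlation matrix (regularize first if non-PD)
#' @param clusters cluster labels from the structural step (length P), or a
#'   P x K binary pattern
#' @param n sample size behind `R`
#' @param mode `"efa"` or `"cfa"`
#' @param ... passed to [fit_efa()] / [fit_cfa()]
#' @return an `fa_fit` with a `fit` component of indices
#' @export
factor_coactivation <- function(R, clusters, n, mode = c("efa", "cfa"), ...) {
  mode <- match.arg(mode)
  if (is.matrix(clusters)) {
    pattern <- clusters
  } else {
    block <- as.integer(factor(clusters))
    pattern <- matrix(0, length(block), max(block))
    pattern[cbind(seq_along(block), block)] <- 1
  }
  K <- ncol(pattern)
  fit <- if (mode == "efa") {
    f0 <- fit_efa(R, K, n, ...)
    if (f0$converged) target_rotate(f0, pattern) else f0
  } else {
    fit_cfa(R, pattern, n, ...)
  }
  fit$pattern <- pattern
  fit$fit <- fit_indices(R, fit, n)
  fit
}

# ---- methods ---------------------------------------------------------------

#' @exportS3Method base::print
print.fa_fit <- function(x, ...) {
  cat(sprintf("%s factor model: P = %d, K = %d%s\n",
              toupper(x$mode), nrow(x$loadings), ncol(x$loadings),
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$fit))
    cat(sprintf("  SRMR = %.4f  RMSEA = %.4f\n", x$fit$srmr, x$fit$rmsea))
  if (length(x$warnings)) cat("  flags:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.fa_fit <- function(object, ...) {
  out <- list(mode = object$mode, P = nrow(object$loadings),
              K = ncol(object$loadings),
              loading_range = range(object$loadings[object$loadings != 0]),
              phi_offdiag = object$phi[upper.tri(object$phi)],
              uniqueness_range = range(object$uniqueness),
              fit = object$fit, warnings = object$warnings,
              converged = object$converged)
  class(out) <- "summary.fa_fit"
  out
}

#' @exportS3Method base::print
print.summary.fa_fit <- function(x, ...) {
  cat(sprintf("%s model, %d variables on %d factors (converged: %s)\n",
              toupper(x$mode), x$P, x$K, x$converged))
  cat(sprintf("  nonzero loadings in [%.3f, %.3f]\n",
              x$loading_range[1], x$loading_range[2]))
  if (length(x$phi_offdiag))
    cat(sprintf("  factor correlations: mean %.3f, range [%.3f, %.3f]\n",
                mean(x$phi_offdiag), min(x$phi_offdiag), max(x$phi_offdiag)))
  cat(sprintf("  uniquenesses in [%.3f, %.3f]\n",
              x$uniqueness_range[1], x$uniqueness_range[2]))
  if (!is.null(x$fit)) print(x$fit)
  if (length(x$warnings)) cat("  flags:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.fa_fit <- function(object, ...) object$loadings

#' @export
fitted.fa_fit <- function(object, ...) implied_sigma(object)

#' @export
residuals.fa_fit <- function(object, R = object$R, ...) {
  if (is.null(R)) stop("no correlation matrix stored; supply R")
  R - implied_sigma(object)
}

#' @export
plot.fa_fit <- function(x, ...) {
  graphics::image(t(x$loadings)[, rev(seq_len(nrow(x$loadings)))],
                  axes = FALSE, main = sprintf("%s loadings", toupper(x$mode)),
                  ...)
  invisible(x)
}
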