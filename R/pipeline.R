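#' Run the two-step structural-functional pipeline
#'
#' Step 1 fits the relational clustering model to the streamline-count
#' matrix (per-subject matrices are averaged and rounded to integers
#' first). Step 2 fits the chosen factor model to every subject-by-task
#' functional dataset, with the Step-1 partition defining the factor pattern
#' for all fits; correlation matrices are ridge-regularized when the series
#' is shorter than the number of ROIs or the matrix is not positive
#' definite. Task-versus-rest Frobenius contrasts and across-task
#' variability summaries are attached, and a behavioral link is estimated
#' when outcomes are supplied.
#'
#' @param streamlines a count matrix, `matrix_table`, or list of per-subject
#'   count matrices (averaged for Step 1)
#' @param functional_runs nested list `subject -> task -> N x P time-series
#'   matrix` (or P x P correlation matrix)
#' @param config a [run_config()]
#' @param behavior optional named list/data.frame of per-subject scalar
#'   outcomes per task for the behavioral link
#' @param rest_task name of the resting-state condition used as reference
#' @return a `study_results` object
#' @export
run_pipeline <- function(streamlines, functional_runs, config = run_config(),
                         behavior = NULL, rest_task = "rest") {
  if (is.list(streamlines) && !inherits(streamlines, "matrix_table")) {
    S <- Reduce(`+`, lapply(streamlines, function(m)
      if (inherits(m, "matrix_table")) m$values else as.matrix(m)))
    S <- round(S / length(streamlines))
  } else S <- if (inherits(streamlines, "matrix_table")) streamlines$values else as.matrix(streamlines)
  step1 <- irm(S, config)
  labels <- step1$partition$labels
  P <- step1$P

  fits <- list()
  regularized <- character(0)
  for (subj in names(functional_runs)) {
    fits[[subj]] <- list()
    for (task in names(functional_runs[[subj]])) {
      dat <- functional_runs[[subj]][[task]]
      if (nrow(dat) == ncol(dat) && ncol(dat) == P &&
          max(abs(dat - t(dat))) < 1e-8 && all(abs(diag(dat) - 1) < 1e-8)) {
        R <- dat
        n_eff <- attr(dat, "n") %||% P
      } else {
        if (ncol(dat) != P) stop("ROI mismatch for subject ", subj, ", task ", task)
        R <- standardize_timeseries(dat)$R
        n_eff <- nrow(dat)
      }
      if (n_eff < P || !is_pd(R)) {
        R <- regularize_correlation(R, config$epsilon)
        regularized <- c(regularized, paste(subj, task, sep = ":"))
      }
      fits[[subj]][[task]] <- factor_coactivation(R, labels, n_eff,
                                                  mode = config$fa_mode)
    }
  }

  frob <- lapply(fits, function(tasks) {
    if (!rest_task %in% names(tasks)) return(NULL)
    rest_phi <- tasks[[rest_task]]$phi
    vapply(setdiff(names(tasks), rest_task), function(tk)
      task_rest_frobenius(tasks[[tk]]$phi, rest_phi), 0)
  })
  variability <- vapply(fits, function(tasks) {
    if (length(tasks) < 2) return(NA_real_)
    across_task_variability(lapply(tasks, function(f) f$phi))
  }, 0)

  link <- NULL
  if (!is.null(behavior)) {
    link <- lapply(names(behavior), function(task) {
      y <- behavior[[task]]
      feats <- t(vapply(names(y), function(subj) {
        phi <- fits[[subj]][[task]]$phi
        phi[lower.tri(phi)]
      }, numeric(sum(lower.tri(fits[[1]][[1]]$phi)))))
      tryCatch(behavioral_link_lasso(feats, unname(unlist(y))),
               error = function(e) list(error = conditionMessage(e)))
    })
    names(link) <- names(behavior)
  }

  structure(list(step1 = step1, fits = fits, pattern_labels = labels,
                 task_rest_frobenius = frob,
                 across_task_sd = variability,
                 behavioral_link = link,
                 regularized = regularized),
            class = "study_results")
}

#' @exportS3Method base::print
print.study_results <- function(x, ...) {
  cat(sprintf("Two-step pipeline results: P = %d, K = %d clusters, %d subject(s)\n",
              x$step1$P, x$step1$partition$K, length(x$fits)))
  ntask <- if (length(x$fits)) length(x$fits[[1]]) else 0
  cat(sprintf("  %d task condition(s) per subject; %d correlation matrices regularized\n",
              ntask, length(x$regularized)))
  if (any(!is.na(x$across_task_sd)))
    cat(sprintf("  across-task SD of mean coactivation: median %.4f\n",
                median(x$across_task_sd, na.rm = TRUE)))
  invisible(x)
}

#' Frobenius contrast between two factor correlation matrices
#'
#' @param phi_task,phi_rest K x K matrices
#' @return the Frobenius norm of their difference
#' @export
task_rest_frobenius <- function(phi_task, phi_rest) {
  if (!all(dim(phi_task) == dim(phi_rest))) stop("dimension mismatch")
  sqrt(sum((phi_task - phi_rest)^2))
}

#' Across-task variability of mean coactivation
#'
#' Computes the mean off-diagonal factor correlation per task, then the
#' standard deviation of these means across tasks.
#'
#' @param phis list of K x K factor correlation matrices (one per task)
#' @return sample standard deviation across tasks
#' @export
across_task_variability <- function(phis) {
  if (length(phis) < 2) stop("need at least two tasks")
  means <- vapply(phis, function(p) mean(p[upper.tri(p)]), 0)
  sd(means)
}

#' L1-penalized link from factor correlations to behavior
#'
#' Lasso regression of a per-subject scalar outcome on the K(K-1)/2
#' factor-correlation features, with the penalty chosen by k-fold
#' cross-validation; predictors with nonzero coefficients at the chosen
#' penalty are reported as selected, and R-squared comes from an ordinary
#' refit on the selected predictors only.
#'
#' @param features subjects x features matrix (standardized internally)
#' @param outcome per-subject scalar outcome
#' @param nfolds cross-validation folds
#' @return list with `selected` (indices), `coefficients` (lasso scale),
#'   `r_squared` (refit on selected), and the chosen `lambda`
#' @export
behavioral_link_lasso <- function(features, outcome, nfolds = 10) {
  features <- as.matrix(features)
  if (nrow(features) < 10) stop("need at least 10 subjects")
  if (sd(outcome) == 0) stop("degenerate outcome: zero variance")
  keep <- apply(features, 2, sd) > 0
  Xs <- scale(features[, keep, drop = FALSE])
  cv <- glmnet::cv.glmnet(Xs, outcome, alpha = 1, nfolds = nfolds)
  co <- as.matrix(glmnet::coef.glmnet(cv, s = "lambda.min"))[-1, 1]
  sel_local <- which(co != 0)
  selected <- which(keep)[sel_local]
  r2 <- 0
  refit_coef <- numeric(0)
  if (length(sel_local)) {
    df <- data.frame(y = outcome, Xs[, sel_local, drop = FALSE])
    refit <- lm(y ~ ., data = df)
    r2 <- summary(refit)$r.squared
    refit_coef <- coef(refit)[-1]
  }
  list(selected = selected, coefficients = co[sel_local],
       refit_coefficients = refit_coef,
       r_squared = r2, lambda = cv$lambda.min)
}
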