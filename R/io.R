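#' Matrix tables with a declared kind
#'
#' A `matrix_table` is a dense numeric matrix with row/column identifiers and a
#' declared `kind` that fixes its validity rules: `counts` entries must be
#' nonnegative integers, `binary` entries must lie in \{0, 1\}, `correlation`
#' matrices must be symmetric with unit diagonal (tolerance 1e-8),
#' `probability` entries must lie in [0, 1]; `loadings` and `timeseries`
#' carry no constraint beyond finiteness.
#'
#' @param values numeric matrix
#' @param kind one of `"counts"`, `"binary"`, `"probability"`,
#'   `"correlation"`, `"loadings"`, `"timeseries"`
#' @param row_ids,col_ids identifiers; default taken from `dimnames(values)`
#'   or generated
#' @return an object of class `matrix_table`
#' @export
matrix_table <- function(values, kind, row_ids = NULL, col_ids = NULL) {
  kind <- match.arg(kind, c("counts", "binary", "probability",
                            "correlation", "loadings", "timeseries"))
  values <- as.matrix(values)
  if (is.null(row_ids)) row_ids <- rownames(values)
  if (is.null(row_ids)) row_ids <- if (nrow(values)) paste0("r", seq_len(nrow(values))) else character(0)
  if (is.null(col_ids)) col_ids <- colnames(values)
  if (is.null(col_ids)) col_ids <- if (ncol(values)) paste0("c", seq_len(ncol(values))) else character(0)
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values))
    stop("row/col id lengths must match matrix dimensions")
  dimnames(values) <- list(as.character(row_ids), as.character(col_ids))
  validate_kind(values, kind)
  structure(list(values = values, row_ids = as.character(row_ids),
                 col_ids = as.character(col_ids), kind = kind),
            class = "matrix_table")
}

validate_kind <- function(values, kind, tol = 1e-8) {
  if (length(values) && any(!is.finite(values)))
    stop("matrix contains non-finite entries")
  bad_cell <- function(sel) {
    idx <- which(sel, arr.ind = TRUE)[1, ]
    sprintf("row %s, column %s (value %g)",
            idx[1], idx[2], values[idx[1], idx[2]])
  }
  if (kind == "counts") {
    bad <- values < 0 | abs(values - round(values)) > tol
    if (any(bad))
      stop("kind 'counts' requires nonnegative integers; offending cell: ", bad_cell(bad))
  } else if (kind == "binary") {
    bad <- !(values %in% c(0, 1))
    if (any(bad))
      stop("kind 'binary' requires entries in {0,1}; offending cell: ", bad_cell(matrix(bad, nrow(values))))
  } else if (kind == "probability") {
    bad <- values < 0 | values > 1
    if (any(bad))
      stop("kind 'probability' requires entries in [0,1]; offending cell: ", bad_cell(bad))
  } else if (kind == "correlation") {
    if (nrow(values) != ncol(values)) stop("correlation matrix must be square")
    if (nrow(values)) {
      if (max(abs(values - t(values))) > tol)
        stop("correlation matrix must be symmetric within tolerance ", tol)
      dbad <- abs(diag(values) - 1) > tol
      if (any(dbad))
        stop("correlation matrix diagonal must be 1 within tolerance ", tol,
             "; offending cell: row ", which(dbad)[1], ", column ", which(dbad)[1],
             " (value ", format(diag(values)[which(dbad)[1]], digits = 12), ")")
    }
  }
  invisible(TRUE)
}

#' @exportS3Method base::print
print.matrix_table <- function(x, ...) {
  cat(sprintf("matrix_table [%d x %d], kind = %s\n",
              nrow(x$values), ncol(x$values), x$kind))
  if (nrow(x$values)) print(x$values[seq_len(min(6, nrow(x$values))),
                                     seq_len(min(6, ncol(x$values))), drop = FALSE])
  invisible(x)
}

#' Read a delimited matrix with identifiers
#'
#' Reads a TSV or CSV matrix whose first row and first column carry
#' identifiers. The delimiter is sniffed from the first line (tab wins over
#' comma). Validation for the declared `kind` is enforced on read.
#'
#' @param path file path
#' @param kind matrix kind, see [matrix_table()]
#' @return a `matrix_table`
#' @export
read_matrix <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {  # empty table
    return(matrix_table(matrix(numeric(0), 0, 0), kind = kind,
                        row_ids = character(0), col_ids = character(0)))
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE, fill = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (length(m) && !is.numeric(m))
    stop("matrix file contains non-numeric entries")
  storage.mode(m) <- "double"
  matrix_table(m, kind = kind, row_ids = rownames(df), col_ids = colnames(df))
}

#' Write a matrix table as TSV
#'
#' Values round-trip through [read_matrix()] to within 1e-12 and identifiers
#' exactly. Count and binary tables are written as integers.
#'
#' @param table a `matrix_table`
#' @param path output file path
#' @export
write_matrix <- function(table, path) {
  stopifnot(inherits(table, "matrix_table"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  v <- table$values
  if (nrow(v) == 0L || ncol(v) == 0L) {
    writeLines(paste(c("id", table$col_ids), collapse = "\t"), path)
    return(invisible(path))
  }
  chr <- if (table$kind %in% c("counts", "binary")) {
    matrix(format(round(v), scientific = FALSE, trim = TRUE), nrow(v))
  } else {
    matrix(formatC(v, digits = 17, format = "g"), nrow(v))
  }
  lines <- c(paste(c("id", table$col_ids), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(table$row_ids[i], chr[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Run configuration with defaults
#'
#' Bundles the clustering hyperparameters, sampler settings and factor-model
#' settings. `xi = NULL` means "resolve to log(P) at fit time", the standard
#' concentration choice for these data. Invariants are checked and violations
#' reported by field name.
#'
#' @param xi CRP concentration (> 0), or `NULL` for log(P) at fit time
#' @param alpha,beta Beta prior parameters for block edge probabilities (> 0)
#' @param delta0,delta1 Dirichlet mass for absent/present edges
#'   (`delta1 > delta0 > 0`)
#' @param iterations,chains,burnin sampler settings
#'   (`iterations > burnin >= 0`)
#' @param seed integer seed or `NULL`
#' @param sm_scans restricted Gibbs scans inside split-merge proposals
#' @param fa_mode `"efa"` or `"cfa"`
#' @param fa_tol,fa_maxit factor-model convergence settings
#' @param epsilon ridge added when regularizing a correlation matrix (>= 0)
#' @return a list of class `run_config`
#' @export
run_config <- function(xi = NULL, alpha = 1, beta = 1, delta0 = 0.1, delta1 = 1,
                       iterations = 6000, chains = 5, burnin = 3000,
                       seed = NULL, sm_scans = 3,
                       fa_mode = "efa", fa_tol = 1e-7, fa_maxit = 1000,
                       epsilon = 0.01) {
  cfg <- list(xi = xi, alpha = alpha, beta = beta, delta0 = delta0,
              delta1 = delta1, iterations = as.integer(iterations),
              chains = as.integer(chains), burnin = as.integer(burnin),
              seed = seed, sm_scans = as.integer(sm_scans),
              fa_mode = match.arg(fa_mode, c("efa", "cfa")),
              fa_tol = fa_tol, fa_maxit = as.integer(fa_maxit),
              epsilon = epsilon)
  if (!is.null(cfg$xi) && cfg$xi <= 0) stop("invalid config field 'xi': must be > 0")
  if (cfg$alpha <= 0) stop("invalid config field 'alpha': must be > 0")
  if (cfg$beta <= 0) stop("invalid config field 'beta': must be > 0")
  if (cfg$delta0 <= 0) stop("invalid config field 'delta0': must be > 0")
  if (cfg$delta1 <= cfg$delta0)
    stop("invalid config field 'delta1': must exceed delta0")
  if (cfg$burnin < 0) stop("invalid config field 'burnin': must be >= 0")
  if (cfg$iterations <= cfg$burnin)
    stop("invalid config field 'iterations': must exceed burnin")
  if (cfg$epsilon < 0) stop("invalid config field 'epsilon': must be >= 0")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from JSON or YAML
#'
#' Unspecified fields take the defaults of [run_config()]; when `P` is given,
#' a missing `xi` is resolved to `log(P)` immediately.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file
#' @param P optional number of ROIs used to resolve `xi = log(P)`
#' @return a `run_config`
#' @export
load_run_config <- function(path, P = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- do.call(run_config, raw[intersect(names(raw), known)])
  if (is.null(cfg$xi) && !is.null(P)) cfg$xi <- log(P)
  cfg
}

#' @exportS3Method base::print
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  cat(sprintf("  xi=%s alpha=%g beta=%g delta0=%g delta1=%g\n",
              if (is.null(x$xi)) "log(P)" else format(x$xi),
              x$alpha, x$beta, x$delta0, x$delta1))
  cat(sprintf("  iterations=%d chains=%d burnin=%d seed=%s\n",
              x$iterations, x$chains, x$burnin,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}
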