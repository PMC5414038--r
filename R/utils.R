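
# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed and a stage tag
#'
#' All randomness in the package flows from one integer seed; each stochastic
#' stage derives its own seed deterministically from the master seed and a
#' short string tag (a counter-based splitting scheme), so stages are
#' individually reproducible and independent of execution order.
#'
#' @param seed master integer seed
#' @param tag character tag naming the consumer (e.g. `"ica"`, `"boot"`)
#' @param counter optional integer for repeated draws under one tag
#' @return an integer seed in `[0, 2^31 - 2]`
#' @export
split_seed <- function(seed, tag, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps results in integer range
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m * 69621 + h * 48271 + counter * 16807) %% m)
}

# Run `expr` under a given seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Column-standardize a matrix (mean 0, sd 1); constant columns yield NaN —
# callers are responsible for screening those out first.
standardize_cols <- function(m) {
  m <- sweep(m, 2L, colMeans(m), `-`)
  sweep(m, 2L, apply(m, 2L, sd), `/`)
}

# Stage-tagged logging to stderr; results never go to stdout.
ml_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Ordinary least squares residuals of each column of `y` on design `X`
# (which must include the intercept if wanted). Errors on rank deficiency,
# naming the aliased columns.
ols_residuals <- function(y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qrX, y)
}

# Build a design matrix from a data.frame of numeric covariates plus an
# intercept. An empty/NULL table gives the intercept-only design.
design_matrix <- function(covariates, n) {
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    return(matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  if (anyNA(covariates)) stop("covariate table contains missing values")
  X <- cbind(`(Intercept)` = 1, data.matrix(covariates))
  X
}
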