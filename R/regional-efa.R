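
#' Parallel analysis for the number of extractable factors
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' eigenvalue distribution of null data of the same shape, obtained by
#' independently permuting each column (breaking all inter-region
#' correlation). The retained count is the number of leading observed
#' eigenvalues that consecutively exceed the chosen quantile of the
#' corresponding null eigenvalue.
#'
#' @param data samples x regions numeric matrix
#' @param n_iter permutation iterations (default 1000; at least 100)
#' @param quantile null quantile (default 0.95)
#' @param seed integer seed
#' @return integer factor count
#' @export
pa_nfactors <- function(data, n_iter = 1000L, quantile = 0.95, seed = 1L) {
  stopifnot(is.matrix(data) || is.data.frame(data), n_iter >= 100L)
  X <- standardize_cols(data.matrix(data))
  n <- nrow(X); p <- ncol(X)
  obs <- eigen(crossprod(X) / (n - 1), symmetric = TRUE,
               only.values = TRUE)$values
  null_eig <- matrix(NA_real_, n_iter, p)
  with_seed(split_seed(seed, "parallel-analysis"), {
    for (b in seq_len(n_iter)) {
      Xp <- apply(X, 2L, sample)
      null_eig[b, ] <- eigen(crossprod(Xp) / (n - 1), symmetric = TRUE,
                             only.values = TRUE)$values
    }
  })
  thr <- apply(null_eig, 2L, stats::quantile, probs = quantile)
  exceeds <- obs > thr
  if (!exceeds[1L]) return(0L)
  as.integer(which.min(c(exceeds, FALSE)) - 1L)
}

#' Exploratory factor analysis by principal-axis factoring
#'
#' Iterated-communality principal-axis solution on the correlation matrix
#' (initial communalities from squared multiple correlations), followed by
#' varimax rotation (Kaiser-normalized). Factors are ordered by decreasing
#' sum of squared loadings and oriented so each factor's
#' largest-magnitude region loads positively. Heywood cases (communality
#' above 1) are clipped to 1 with a warning and flagged.
#'
#' @param data samples x regions numeric matrix (typically regional
#'   thickness already adjusted for sex, intracranial volume, batch and age
#'   via [residualize()])
#' @param n_factors number of factors to extract (e.g. from
#'   [pa_nfactors()])
#' @param max_iter,tol communality-iteration controls
#' @return a `factor_model`: rotated `loadings` (regions x factors),
#'   `communalities`, `variance_explained` (per-factor fractions of total
#'   region variance), Thurstone regression `score_weights`, the training
#'   `center`/`scale`, and a `heywood` flag
#' @export
fit_efa <- function(data, n_factors, max_iter = 1000L, tol = 1e-8) {
  X <- data.matrix(data)
  p <- ncol(X)
  stopifnot(n_factors >= 1L, n_factors < p)
  ctr <- colMeans(X); scl <- apply(X, 2L, sd)
  if (any(scl == 0)) stop("constant region column")
  Z <- sweep(sweep(X, 2L, ctr, `-`), 2L, scl, `/`)
  R <- crossprod(Z) / (nrow(Z) - 1)
  h2 <- tryCatch(1 - 1 / diag(solve(R)),        # SMC start
                 error = function(e) {
                   # singular R (e.g. noiseless factor structure): fall back
                   # to the largest absolute off-diagonal correlation
                   ml_log("efa", "singular correlation matrix; max-|r| start")
                   diag(R) <- 0
                   h2 <- apply(abs(R), 1L, max)
                   diag(R) <- 1
                   h2
                 })
  heywood <- FALSE
  for (it in seq_len(max_iter)) {
    Rr <- R; diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(n_factors)], 0)), n_factors)
    h2_new <- rowSums(L^2)
    if (any(h2_new > 1 + 1e-8)) heywood <- TRUE
    h2_new <- pmin(h2_new, 1)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  if (heywood) warning("Heywood case: communalities clipped to 1")
  rot <- if (n_factors > 1L) .varimax_multistart(L) else L
  ss <- colSums(rot^2)
  ord <- order(-ss)
  rot <- rot[, ord, drop = FALSE]
  sgn <- vapply(seq_len(n_factors), function(j) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] >= 0) 1 else -1
  }, numeric(1))
  rot <- sweep(rot, 2L, sgn, `*`)
  dimnames(rot) <- list(colnames(X) %||% sprintf("region_%02d", seq_len(p)),
                        sprintf("F%d", seq_len(n_factors)))
  W <- tryCatch(solve(R, rot), error = function(e) {
    ml_log("efa", "singular correlation matrix; ridge fallback eps = 1e-8")
    solve(R + diag(1e-8, p), rot)
  })
  dimnames(W) <- dimnames(rot)
  structure(list(loadings = rot, n_factors = n_factors,
                 communalities = setNames(rowSums(rot^2), rownames(rot)),
                 score_weights = W,
                 variance_explained = setNames(colSums(rot^2) / p,
                                               colnames(rot)),
                 rotation = if (n_factors > 1L) "varimax" else "none",
                 center = ctr, scale = scl, heywood = heywood),
            class = "factor_model")
}

# stats::varimax can stall on the symmetric stationary point of the
# unrotated solution; restart it from a few fixed orthogonal bases and keep
# the rotation with the best (Kaiser-normalized) varimax criterion
.varimax_multistart <- function(L) {
  q <- ncol(L)
  crit <- function(M) {
    Mn <- M / sqrt(pmax(rowSums(M^2), 1e-12))
    sum(apply(Mn^2, 2L, function(x) sum((x - mean(x))^2)))
  }
  starts <- list(diag(q))
  for (s in 1:3)
    starts[[s + 1L]] <- qr.Q(qr(matrix(sin(seq_len(q * q) * s * 0.7 + s),
                                       q, q)))
  best <- NULL; best_c <- -Inf
  for (Q in starts) {
    vm <- stats::varimax(L %*% Q, normalize = TRUE)
    cand <- matrix(vm$loadings, nrow(L), q)
    cc <- crit(cand)
    if (cc > best_c) { best <- cand; best_c <- cc }
  }
  best
}

#' @export
print.factor_model <- function(x, loading_cutoff = 0.3, ...) {
  cat(sprintf(
    "factor_model: %d factors over %d regions (%s); %.1f%% variance\n",
    x$n_factors, nrow(x$loadings), x$rotation,
    100 * sum(x$variance_explained)))
  L <- round(x$loadings, 2)
  L[abs(L) < loading_cutoff] <- NA          # display rule: |loading| >= 0.3
  print(head(L, 12))
  if (nrow(L) > 12) cat("  ...", nrow(L) - 12, "more regions\n")
  invisible(x)
}

#' Loadings table under the display rule
#'
#' @param model a `factor_model`
#' @param cutoff minimum absolute loading to report (default 0.3)
#' @return data.frame region, factor, loading for loadings passing the rule
#' @export
efa_loading_table <- function(model, cutoff = 0.3) {
  idx <- which(abs(model$loadings) >= cutoff, arr.ind = TRUE)
  data.frame(region = rownames(model$loadings)[idx[, 1L]],
             factor = colnames(model$loadings)[idx[, 2L]],
             loading = model$loadings[idx], stringsAsFactors = FALSE)
}

#' Regression-method (Thurstone) factor scores
#'
#' Applies the training solution's score weights `W = R^-1 Lambda` to data
#' standardized with the *training* sample's means and sds — so a second
#' sample can be scored on the factor solution inferred from the first.
#'
#' @param model a `factor_model`
#' @param data samples x regions matrix with the same region columns
#' @return samples x factors score matrix
#' @export
efa_scores <- function(model, data) {
  X <- data.matrix(data)
  if (!is.null(colnames(X)) && !is.null(rownames(model$loadings))) {
    if (!all(rownames(model$loadings) %in% colnames(X)))
      stop("data lacks regions present in the factor model")
    X <- X[, rownames(model$loadings), drop = FALSE]
  }
  Z <- sweep(sweep(X, 2L, model$center, `-`), 2L, model$scale, `/`)
  Z %*% model$score_weights
}
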