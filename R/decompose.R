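
#' Estimate the number of components by Random Matrix Theory
#'
#' Counts eigenvalues of the sample covariance of the standardized matrix
#' that exceed the Marchenko-Pastur bulk upper edge. For `n <= p` the
#' covariance is taken across features (`X X' / p`, edge
#' `(1 + sqrt(n/p))^2`); for `p < n` the roles of `n` and `p` are swapped —
#' the estimator is symmetric in the two dimensions.
#'
#' @param X a [residual_matrix()] or a numeric samples-x-features matrix
#'   (columns are standardized internally when a plain matrix is given)
#' @return integer component count, `0 <= k < n_samples`
#' @export
estimate_k_rmt <- function(X) {
  v <- if (inherits(X, "residual_matrix")) X$values else X
  stopifnot(is.matrix(v), nrow(v) >= 3L)
  if (!inherits(X, "residual_matrix")) {
    sds <- apply(v, 2L, sd)
    v <- v[, sds > 1e-12, drop = FALSE]
    v <- standardize_cols(v)
  }
  n <- nrow(v); p <- ncol(v)
  if (n <= p) {
    ev <- eigen(tcrossprod(v) / p, symmetric = TRUE, only.values = TRUE)$values
    edge <- (1 + sqrt(n / p))^2
  } else {
    ev <- eigen(crossprod(v) / n, symmetric = TRUE, only.values = TRUE)$values
    edge <- (1 + sqrt(p / n))^2
  }
  as.integer(sum(ev > edge))
}

# logcosh contrast derivatives for the fixed-point update
.ica_g <- function(u) tanh(u)
.ica_dg <- function(u) 1 - tanh(u)^2

# symmetric decorrelation W <- (W W')^{-1/2} W
.sym_orth <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors) %*% W
}

#' Run multi-restart FastICA on a residual matrix
#'
#' Decomposes `X (n x p) = A (n x k) %*% S (k x p)` where rows of `S`
#' (CpG loadings) are the maximally non-gaussian sources. The data are
#' whitened once via the eigendecomposition of `X X' / p` (whitening is
#' deterministic; only the orthogonal rotation is re-estimated per restart),
#' then each restart runs the symmetric fixed-point iteration with the
#' log-cosh contrast. Non-converged restarts are flagged and excluded from
#' clustering, with a logged count.
#'
#' @param X a [residual_matrix()] (or standardized matrix)
#' @param k number of components; `"auto"` uses [estimate_k_rmt()]
#' @param n_restarts number of random restarts (study convention: 30)
#' @param seed integer seed controlling the restart initialisations
#' @param tol,maxit fixed-point convergence tolerance and iteration cap
#' @return an `ica_runs` collection for [cluster_runs()]
#' @export
run_ica <- function(X, k = "auto", n_restarts = 30L, seed = 1L,
                    tol = 1e-6, maxit = 500L) {
  v <- if (inherits(X, "residual_matrix")) X$values else X
  stopifnot(is.matrix(v), n_restarts >= 1L)
  n <- nrow(v); p <- ncol(v)
  if (identical(k, "auto")) {
    k <- estimate_k_rmt(X)
    ml_log("decompose", "RMT estimated k = %d", k)
  }
  k <- as.integer(k)
  if (k < 1L || k > min(n, p)) stop("k must satisfy 1 <= k <= min(n, p)")
  eg <- eigen(tcrossprod(v) / p, symmetric = TRUE)
  d <- eg$values[seq_len(k)]
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  Z <- diag(1 / sqrt(d), k) %*% t(U) %*% v      # whitened, k x p
  runs <- vector("list", n_restarts)
  with_seed(split_seed(seed, "ica"), {
    for (r in seq_len(n_restarts)) {
      W <- .sym_orth(matrix(rnorm(k * k), k, k))
      converged <- FALSE
      for (it in seq_len(maxit)) {
        WZ <- W %*% Z
        G <- .ica_g(WZ)
        W1 <- tcrossprod(G, Z) / p - diag(rowMeans(.ica_dg(WZ)), k) %*% W
        W1 <- .sym_orth(W1)
        delta <- max(abs(1 - abs(diag(W1 %*% t(W)))))
        W <- W1
        if (delta < tol) { converged <- TRUE; break }
      }
      A <- U %*% diag(sqrt(d), k) %*% t(W)
      S <- W %*% Z
      runs[[r]] <- list(A = A, S = S, converged = converged)
    }
  })
  n_conv <- sum(vapply(runs, `[[`, logical(1), "converged"))
  if (n_conv == 0L)
    stop("no ICA restart converged; consider a lower k")
  if (n_conv < n_restarts)
    ml_log("decompose", "%d of %d restarts did not converge (excluded)",
           n_restarts - n_conv, n_restarts)
  structure(list(runs = runs, X = v, k = k, n_restarts = n_restarts,
                 seed = seed,
                 sample_ids = rownames(v), cpg_ids = colnames(v)),
            class = "ica_runs")
}

# orient each loadings row to positive skewness; near-zero skew falls back
# to making the largest-magnitude loading positive. Returns sign vector.
.component_signs <- function(S) {
  vapply(seq_len(nrow(S)), function(j) {
    s <- S[j, ]
    sk <- mean((s - mean(s))^3) / sd(s)^3
    if (abs(sk) > 1e-12) sign(sk)
    else {
      i <- which.max(abs(s))
      if (s[i] >= 0) 1 else -1
    }
  }, numeric(1))
}

#' Cluster ICA restarts into centrotype components
#'
#' Pools the mixing-matrix columns of all converged restarts, clusters them
#' by complete-linkage hierarchical clustering on the distance
#' `1 - |Pearson r|`, cuts the tree at `k` clusters, and takes each
#' cluster's centrotype — the member with maximal summed similarity to its
#' cluster — as the final component. Loadings are then re-estimated by least
#' squares from the data and the final mixing matrix, scaled to unit-sd
#' rows, and oriented to positive loading skewness.
#'
#' @param runs an `ica_runs` collection from [run_ica()]
#' @param k number of clusters; defaults to the decomposition order
#' @return an `ica_model` with fields `A` (samples x k mixing weights), `S`
#'   (k x CpGs loadings), per-component `stability` (mean within-cluster
#'   `|r|`) and `dominance` (largest single-sample share of weight
#'   variance), and `retained` flags (all `TRUE` until
#'   [filter_dominant()])
#' @export
cluster_runs <- function(runs, k = runs$k) {
  stopifnot(inherits(runs, "ica_runs"))
  conv <- Filter(function(r) r$converged, runs$runs)
  if (!length(conv)) stop("no converged runs to cluster")
  pooled <- do.call(cbind, lapply(conv, `[[`, "A"))
  if (k > ncol(pooled))
    stop("k exceeds the number of pooled mixing columns")
  sim <- abs(cor(pooled))
  cl <- if (ncol(pooled) == 1L) 1L
        else cutree(hclust(as.dist(1 - sim), method = "complete"), k = k)
  cent <- integer(k); stab <- numeric(k)
  for (j in seq_len(k)) {
    members <- which(cl == j)
    block <- sim[members, members, drop = FALSE]
    cent[j] <- members[which.max(rowSums(block))]
    stab[j] <- if (length(members) > 1L)
      mean(block[upper.tri(block)]) else 1
  }
  ord <- order(-stab)
  cent <- cent[ord]; stab <- stab[ord]
  A <- pooled[, cent, drop = FALSE]
  S <- solve(crossprod(A), crossprod(A, runs$X))
  f <- apply(S, 1L, sd)
  if (any(f < 1e-12)) stop("degenerate component with zero loading variance")
  S <- S / f
  A <- A %*% diag(f, k)
  sgn <- .component_signs(S)
  S <- S * sgn
  A <- A %*% diag(sgn, k)
  dimnames(S) <- list(paste0("IC", seq_len(k)), runs$cpg_ids)
  dimnames(A) <- list(runs$sample_ids, paste0("IC", seq_len(k)))
  model <- structure(
    list(A = A, S = S, k = k, n_restarts = runs$n_restarts,
         stability = setNames(stab, colnames(A)),
         dominance = setNames(.dominance(A), colnames(A)),
         retained = setNames(rep(TRUE, k), colnames(A)),
         seed = runs$seed),
    class = "ica_model")
  model
}

.dominance <- function(A) {
  ss <- colSums(A^2)
  if (any(ss == 0)) stop("zero-variance component column")
  apply(A^2, 2L, max) / ss
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("ica_model: k=%d components over %d samples x %d CpGs\n",
              x$k, nrow(x$A), ncol(x$S)))
  cat(sprintf("  retained %d/%d; stability %.3f-%.3f; dominance %.3f-%.3f\n",
              sum(x$retained), x$k, min(x$stability), max(x$stability),
              min(x$dominance), max(x$dominance)))
  invisible(x)
}

#' Flag components dominated by single individuals
#'
#' A component's dominance is the largest single-sample share of its weight
#' variance, `max_i a_ij^2 / sum_i a_ij^2`. Components whose dominance
#' exceeds the threshold represent singular modes of variation and are
#' flagged `retained = FALSE` (default threshold: 10%). `A` and `S` are not
#' mutated.
#'
#' @param model an `ica_model`
#' @param threshold dominance threshold in `(0, 1]`
#' @return the model with updated `retained` flags
#' @export
filter_dominant <- function(model, threshold = 0.10) {
  stopifnot(inherits(model, "ica_model"), threshold > 0, threshold <= 1)
  dom <- .dominance(model$A)
  model$dominance <- setNames(dom, colnames(model$A))
  model$retained <- setNames(dom <= threshold, colnames(model$A))
  ml_log("decompose", "dominance filter: %d of %d components retained",
         sum(model$retained), model$k)
  model
}

#' Extract one component's per-sample pattern
#'
#' @param model an `ica_model`
#' @param component_id component name (e.g. `"IC2"`) or index
#' @return a `component_pattern`: the sample weight vector with its
#'   stability and dominance diagnostics
#' @export
component_pattern <- function(model, component_id) {
  stopifnot(inherits(model, "ica_model"))
  j <- if (is.character(component_id)) match(component_id, colnames(model$A))
       else as.integer(component_id)
  if (is.na(j) || j < 1L || j > model$k) stop("unknown component: ",
                                              component_id)
  structure(list(weights = model$A[, j],
                 component_id = colnames(model$A)[j],
                 stability = model$stability[[j]],
                 dominance = model$dominance[[j]]),
            class = "component_pattern")
}

#' Full decomposition convenience wrapper
#'
#' RMT order estimation, `n_restarts` FastICA runs, centrotype clustering
#' and the dominance filter in one call.
#'
#' @inheritParams run_ica
#' @param dominance dominance threshold for [filter_dominant()]
#' @return an `ica_model`
#' @export
decompose_methylome <- function(X, k = "auto", n_restarts = 30L,
                                dominance = 0.10, seed = 1L) {
  runs <- run_ica(X, k = k, n_restarts = n_restarts, seed = seed)
  model <- cluster_runs(runs)
  filter_dominant(model, dominance)
}
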