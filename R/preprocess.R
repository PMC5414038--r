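
#' Filter CpGs by missing rate
#'
#' Removes CpGs whose missing rate is greater than or equal to
#' `max_missing_rate` (default mirrors the usual "missing rate >= 5%" QC
#' rule), preserving the order of survivors.
#'
#' @param betas a [beta_matrix()]
#' @param max_missing_rate fraction in `[0, 1]`
#' @param exclude optional character vector of CpG IDs to drop outright
#'   (e.g. a cross-hybridizing/polymorphic probe blacklist)
#' @return the filtered [beta_matrix()]
#' @export
filter_cpgs <- function(betas, max_missing_rate = 0.05, exclude = NULL) {
  stopifnot(inherits(betas, "beta_matrix"),
            max_missing_rate >= 0, max_missing_rate <= 1)
  v <- betas$values
  keep <- rep(TRUE, ncol(v))
  if (!is.null(exclude)) keep <- keep & !(colnames(v) %in% exclude)
  rate <- colMeans(is.na(v))
  # threshold 1.0 is vacuous (rate can reach 1 only for all-missing CpGs,
  # which the rate >= threshold rule still removes unless threshold > 1)
  if (max_missing_rate < 1) keep <- keep & (rate < max_missing_rate)
  if (!any(keep)) stop("all CpGs removed by missing-rate filter")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    ml_log("preprocess", "filter_cpgs: removed %d of %d CpGs", n_drop, ncol(v))
  beta_matrix(v[, keep, drop = FALSE])
}

#' Impute missing beta values by k-nearest-neighbour samples
#'
#' For each missing entry, the `k` nearest samples (Euclidean distance over
#' mutually observed CpGs, scaled to the number of shared CpGs) with an
#' observed value at that CpG are averaged. Observed entries are never
#' touched; imputed entries are convex combinations of observed betas and so
#' stay in `[0, 1]`.
#'
#' @param betas a [beta_matrix()]
#' @param k number of neighbours (default 10)
#' @return a complete [beta_matrix()]
#' @export
impute_knn <- function(betas, k = 10L) {
  stopifnot(inherits(betas, "beta_matrix"), k >= 1)
  v <- betas$values
  if (!anyNA(v)) return(betas)
  if (any(colSums(!is.na(v)) == 0L))
    stop("CpG with no observed values; run filter_cpgs first")
  n <- nrow(v)
  obs <- !is.na(v)
  v0 <- v; v0[!obs] <- 0
  # pairwise scaled squared distances over shared observed CpGs
  cross <- tcrossprod(v0)                 # sum x_i x_j over shared (0 elsewhere)
  sq <- tcrossprod(v0^2, obs * 1)         # sum x_i^2 over CpGs observed in both
  shared <- tcrossprod(obs * 1)           # number of shared observed CpGs
  d2 <- sq + t(sq) - 2 * cross
  d2 <- d2 / pmax(shared, 1L)             # mean squared difference
  d2[shared == 0L] <- Inf
  diag(d2) <- Inf
  for (i in which(rowSums(!obs) > 0L)) {
    ord <- order(d2[i, ])
    for (j in which(!obs[i, ])) {
      donors <- ord[obs[ord, j]]
      if (!length(donors)) stop("no donor sample for CpG ", colnames(v)[j])
      v[i, j] <- mean(v[head(donors, k), j])
    }
  }
  beta_matrix(v)
}

#' Estimate surrogate variables preserving a protected covariate
#'
#' A two-step stand-in for iteratively re-weighted surrogate variable
#' analysis: (1) residualize the beta matrix against the known covariates
#' *and* the protected covariate (so every surrogate is orthogonal to the
#' protected variable by construction, preserving e.g. chronological age
#' effects); (2) take the leading left singular vectors of the standardized
#' residual matrix. With `n_sv = "auto"` the count comes from the
#' Random-Matrix-Theory estimator ([estimate_k_rmt()]).
#'
#' @param betas a complete [beta_matrix()] (or plain numeric matrix)
#' @param protected numeric vector aligned to samples (e.g. age at blood
#'   sampling) whose signal the surrogates must not absorb
#' @param known optional data.frame of known covariates (e.g. sex)
#' @param n_sv surrogate count, or `"auto"`
#' @return data.frame of surrogate columns `sv1..svK` (possibly 0 columns)
#' @export
estimate_svs <- function(betas, protected, known = NULL, n_sv = "auto") {
  v <- if (inherits(betas, "beta_matrix")) betas$values else betas
  stopifnot(is.matrix(v), !anyNA(v), length(protected) == nrow(v))
  n <- nrow(v)
  X <- design_matrix(cbind(known, protected = protected), n)
  rankX <- qr(X)$rank
  res <- ols_residuals(v, X)
  sds <- apply(res, 2L, sd)
  res <- res[, sds > 1e-12, drop = FALSE]
  res <- standardize_cols(res)
  if (identical(n_sv, "auto")) {
    n_sv <- estimate_k_rmt(res)
    ml_log("preprocess", "estimate_svs: RMT chose %d surrogate(s)", n_sv)
  }
  n_sv <- as.integer(n_sv)
  if (n_sv >= n - rankX)
    stop("n_sv must be < n_samples - rank(known covariates) = ", n - rankX)
  if (n_sv == 0L)
    return(data.frame(matrix(numeric(0), nrow = n, ncol = 0)))
  sv <- svd(res, nu = n_sv, nv = 0L)$u
  as.data.frame(setNames(as.data.frame(sv), paste0("sv", seq_len(n_sv))))
}

#' Residualize a beta matrix against covariates and standardize
#'
#' Per-CpG ordinary-least-squares residuals on the covariate design (plus
#' intercept), standardized across samples to mean 0 and sd 1 — the matrix
#' that ICA decomposes. CpGs left with (numerically) zero residual variance
#' are dropped with a warning, since their standardization is undefined.
#'
#' @param betas a [beta_matrix()] or plain samples-x-features numeric matrix
#' @param covariates data.frame of numeric covariates (may be `NULL` /
#'   0-column for intercept-only adjustment, i.e. plain z-scoring)
#' @param n_sv number of surrogate columns included in `covariates`
#'   (bookkeeping only, recorded on the result)
#' @return a [residual_matrix()]
#' @export
residualize <- function(betas, covariates = NULL, n_sv = 0L) {
  v <- if (inherits(betas, "beta_matrix")) betas$values
       else if (inherits(betas, "residual_matrix")) betas$values
       else betas
  stopifnot(is.matrix(v))
  if (anyNA(v)) stop("missing values present; impute first")
  X <- design_matrix(covariates, nrow(v))
  res <- ols_residuals(v, X)
  sds <- apply(res, 2L, sd)
  degenerate <- sds < 1e-12 * pmax(1, apply(abs(v), 2L, max))
  if (any(degenerate)) {
    warning(sum(degenerate),
            " CpG(s) with zero residual variance dropped: ",
            paste(head(colnames(v)[degenerate], 5L), collapse = ", "),
            if (sum(degenerate) > 5L) ", ..." else "")
    res <- res[, !degenerate, drop = FALSE]
  }
  residual_matrix(standardize_cols(res),
                  adjusted_for = setdiff(colnames(X), "(Intercept)"),
                  n_sv = n_sv)
}

#' One-call preprocessing: filter, impute, surrogate estimation, residualize
#'
#' @param betas a [beta_matrix()]
#' @param protected numeric vector (e.g. age at blood draw) protected from
#'   surrogate absorption
#' @param known data.frame of known covariates entering the adjustment
#'   (e.g. sex)
#' @param max_missing_rate,k_neighbours,n_sv stage parameters
#' @param exclude optional CpG blacklist
#' @return list with `residuals` (a [residual_matrix()]) and `manifest`
#'   (covariates used, surrogate count, CpGs dropped)
#' @export
preprocess_betas <- function(betas, protected, known = NULL,
                             max_missing_rate = 0.05, k_neighbours = 10L,
                             n_sv = "auto", exclude = NULL) {
  p0 <- ncol(betas$values)
  betas <- filter_cpgs(betas, max_missing_rate, exclude = exclude)
  betas <- impute_knn(betas, k_neighbours)
  sv <- estimate_svs(betas, protected = protected, known = known, n_sv = n_sv)
  covs <- if (ncol(sv)) cbind(known, sv) else known
  res <- residualize(betas, covs, n_sv = ncol(sv))
  list(residuals = res,
       manifest = list(n_cpgs_in = p0, n_cpgs_out = ncol(res$values),
                       covariates = res$adjusted_for, n_sv = ncol(sv),
                       max_missing_rate = max_missing_rate,
                       k_neighbours = k_neighbours))
}
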