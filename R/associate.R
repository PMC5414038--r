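
#' Pearson association with explicit Bonferroni family
#'
#' Pearson correlation with a t-distributed test (`n - 2` d.f.), one- or
#' two-sided, and Bonferroni correction by an explicitly stated family size.
#' The family is always an argument, never inferred: decomposition-based
#' analyses use one family per set of components tested (e.g. 15 retained
#' components; 8 thickness factors).
#'
#' @param x,y aligned numeric sample vectors (pairs with missing values are
#'   dropped)
#' @param sidedness `"two"` (default), `"less"` (lower tail) or
#'   `"greater"`
#' @param n_tests Bonferroni family size
#' @param adjusted_for character record of covariates already removed
#' @return an `assoc_result`: `r`, `p_nominal`,
#'   `p_corrected = min(1, p_nominal * n_tests)`, `n_obs`, `df`
#' @export
assoc_cor <- function(x, y, sidedness = c("two", "less", "greater"),
                      n_tests = 1L, adjusted_for = character()) {
  sidedness <- match.arg(sidedness)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  r <- cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.xmin))
  p <- switch(sidedness,
              two = 2 * pt(-abs(tt), df = n - 2),
              less = pt(tt, df = n - 2),
              greater = pt(tt, df = n - 2, lower.tail = FALSE))
  structure(list(r = r, p_nominal = p,
                 p_corrected = min(1, p * n_tests),
                 n_tests = as.integer(n_tests), n_obs = n, df = n - 2,
                 sidedness = sidedness, adjusted_for = adjusted_for),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf(
    "r = %.4f (n = %d, %s-sided): p = %.3g, Bonferroni x%d: p = %.3g\n",
    x$r, x$n_obs, x$sidedness, x$p_nominal, x$n_tests, x$p_corrected))
  if (length(x$adjusted_for))
    cat("  adjusted for:", paste(x$adjusted_for, collapse = ", "), "\n")
  invisible(x)
}

#' Bonferroni correction over an explicit family
#'
#' @param p nominal p-value(s)
#' @param n_tests family size
#' @return `min(1, p * n_tests)`, vectorized
#' @export
bonferroni <- function(p, n_tests) pmin(1, p * n_tests)

#' Partial a covariate set out of a sample vector
#'
#' OLS residual of `x` on the covariate design (with intercept); the result
#' is orthogonal to every covariate column. With an empty covariate set the
#' result is the mean-centred `x`.
#'
#' @param x numeric sample vector
#' @param z covariate table (data.frame/matrix/vector) or `NULL`
#' @return residual vector of the same length
#' @export
partial_out <- function(x, z = NULL) {
  n <- length(x)
  if (!is.null(z) && !is.data.frame(z)) z <- as.data.frame(z)
  X <- design_matrix(z, n)
  drop(ols_residuals(matrix(x, ncol = 1L), X))
}

#' Correlation after asymmetric covariate adjustment
#'
#' Partials `z_x` out of `x` and `z_y` out of `y` before the Pearson test —
#' the double-partialling used when two age variables exist (age at blood
#' draw removed from the methylomic pattern, age at assessment removed from
#' the phenotype), and equally the symmetric cell-count adjustment when
#' `z_x = z_y`. With identical covariate sets this equals the textbook
#' first-order partial correlation.
#'
#' @inheritParams assoc_cor
#' @param z_x,z_y covariate tables for `x` and `y` (either may be `NULL`)
#' @return an `assoc_result`
#' @export
adjusted_cor <- function(x, y, z_x = NULL, z_y = NULL,
                         sidedness = "two", n_tests = 1L) {
  nm <- c(if (!is.null(z_x)) paste0("x:", colnames(as.data.frame(z_x))),
          if (!is.null(z_y)) paste0("y:", colnames(as.data.frame(z_y))))
  assoc_cor(partial_out(x, z_x), partial_out(y, z_y),
            sidedness = sidedness, n_tests = n_tests,
            adjusted_for = nm %||% character())
}

#' Nested F-test: does a predictor add to a polynomial age model?
#'
#' Compares the fit of `y ~ poly(age, degree)` against the same model
#' augmented by one added predictor — the guard against the added variable
#' merely proxying non-linear age effects. The polynomial basis is centred
#' and orthogonalised (`stats::poly`), since raw powers of age are
#' near-collinear; the test depends only on the model subspace.
#'
#' @param y response sample vector
#' @param age the polynomial base variable
#' @param added the candidate predictor
#' @param degree polynomial degree (default 5)
#' @return list with `F`, `df1` (= 1), `df2` (= n - degree - 2), `p`
#' @export
poly_age_ftest <- function(y, age, added, degree = 5L) {
  n <- length(y)
  stopifnot(length(age) == n, length(added) == n)
  if (n <= degree + 3L) stop("need n > degree + 3 observations")
  P <- stats::poly(age, degree = degree)
  X0 <- cbind(1, P)
  X1 <- cbind(X0, added)
  if (qr(X1)$rank < ncol(X1))
    stop("added predictor is collinear with the polynomial age basis")
  rss0 <- sum(qr.resid(qr(X0), y)^2)
  rss1 <- sum(qr.resid(qr(X1), y)^2)
  df2 <- n - degree - 2L
  Fstat <- (rss0 - rss1) / (rss1 / df2)
  list(F = Fstat, df1 = 1L, df2 = df2,
       p = pf(Fstat, 1L, df2, lower.tail = FALSE))
}

#' Associate every retained component with a set of phenotypes
#'
#' Runs [assoc_cor()] (optionally with double age partialling via
#' [adjusted_cor()]) for each retained component against each phenotype
#' column, with the Bonferroni family set to the number of retained
#' components.
#'
#' @param model an `ica_model`
#' @param phenotypes data.frame of numeric phenotype columns (aligned to the
#'   model's samples)
#' @param z_x,z_y optional covariate tables partialled out of the component
#'   weights and the phenotypes respectively
#' @return data.frame: component, phenotype, n, r, p_nominal, n_tests,
#'   p_corrected
#' @export
associate_components <- function(model, phenotypes, z_x = NULL, z_y = NULL) {
  stopifnot(inherits(model, "ica_model"))
  comps <- names(which(model$retained))
  fam <- length(comps)
  rows <- list()
  for (cc in comps) for (ph in colnames(phenotypes)) {
    res <- adjusted_cor(model$A[, cc], phenotypes[[ph]],
                        z_x = z_x, z_y = z_y, n_tests = fam)
    rows[[length(rows) + 1L]] <- data.frame(
      component = cc, phenotype = ph, n = res$n_obs, r = res$r,
      p_nominal = res$p_nominal, n_tests = fam,
      p_corrected = res$p_corrected, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
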