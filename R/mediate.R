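
# standardized three-variable mediation estimates from raw vectors:
# a = r(x, m); (c', b) = OLS of y on (x, m); c = r(x, y); indirect = a * b.
.mediation_point <- function(x, m, y) {
  a <- cor(x, m)
  r_my <- cor(m, y)
  r_xy <- cor(x, y)
  b <- (r_my - a * r_xy) / (1 - a^2)
  c_prime <- (r_xy - a * r_my) / (1 - a^2)
  c(a = a, b = b, c = r_xy, c_prime = c_prime, indirect = a * b,
    r_my = r_my)
}

#' Kappa-squared mediation effect size
#'
#' The observed indirect effect `|a * b|` as a fraction of the maximum
#' `|a * b|` attainable under the positive-semidefiniteness constraint on
#' the 3x3 correlation matrix of (x, m, y), following the Preacher-Kelley
#' construction: `|a|` is maximised over the permissible `r(x, m)` holding
#' the other two correlations fixed, `|b|` over the permissible `r(m, y)`,
#' each with the sign of the observed path. (The known critique of this
#' construction — the two maxima are not jointly attainable — is documented
#' in the vignette; the construction itself is what is implemented.)
#'
#' @param r_xm,r_my,r_xy the three Pearson correlations
#' @return kappa-squared in `[0, 1]`
#' @export
kappa_squared <- function(r_xm, r_my, r_xy) {
  det3 <- 1 + 2 * r_xm * r_my * r_xy - r_xm^2 - r_my^2 - r_xy^2
  if (det3 < -1e-10) stop("correlation triple is not positive semi-definite")
  a <- r_xm
  b <- (r_my - r_xm * r_xy) / (1 - r_xm^2)
  if (a == 0 || b == 0) return(0)
  half_a <- sqrt(max(0, (1 - r_xy^2) * (1 - r_my^2)))
  bound_a <- r_xy * r_my + sign(a) * half_a     # PSD boundary, matching sign
  max_b <- sqrt((1 - r_xy^2) / (1 - r_xm^2))    # |b| at the r_my boundary
  denom <- abs(bound_a) * max_b
  if (denom == 0) return(0)
  min(1, abs(a * b) / denom)
}

#' Standardized mediation analysis with BCa bootstrap
#'
#' Estimates the standardized paths of the three-variable mediation model
#' (x -> m -> y): `a` (x on the mediator), `b` (mediator on the outcome
#' controlling x), total effect `c`, direct effect `c'`, the indirect
#' effect `a * b` and [kappa_squared()]. With `n_boot > 0`, case-resampling
#' bootstrap confidence intervals for the indirect effect and kappa-squared
#' are computed with bias-correction (from the bootstrap CDF at the point
#' estimate) and acceleration (from jackknife skewness). Significance of the
#' indirect effect is the smallest `1 - level` over
#' `levels = {0.90, 0.95, 0.99, 0.999}` at which the BCa interval excludes
#' zero.
#'
#' @param x,m,y cause, mediator and outcome sample vectors
#' @param n_boot bootstrap resamples (0 skips the bootstrap; at least 1,000
#'   required for CI output)
#' @param ci_level confidence level for the reported intervals
#' @param seed integer seed for the resampling
#' @param scan_levels CI levels scanned for the significance call
#' @return a `mediation_result` with paths, `indirect`, `kappa2`, bootstrap
#'   CIs, `significant` flag and scan-based `p_value`
#' @export
mediate <- function(x, m, y, n_boot = 10000L, ci_level = 0.999, seed = 1L,
                    scan_levels = c(0.90, 0.95, 0.99, 0.999)) {
  ok <- complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete observations")
  if (sd(x) == 0 || sd(m) == 0 || sd(y) == 0) stop("constant input vector")
  est <- .mediation_point(x, m, y)
  k2 <- kappa_squared(est[["a"]], est[["r_my"]], est[["c"]])
  out <- list(a = est[["a"]], b = est[["b"]], c = est[["c"]],
              c_prime = est[["c_prime"]], indirect = est[["indirect"]],
              kappa2 = k2, n_obs = n, n_boot = as.integer(n_boot),
              ci_level = ci_level, seed = seed)
  if (n_boot > 0L) {
    if (n_boot < 1000L) stop("n_boot must be >= 1000 for CI output")
    boot <- matrix(NA_real_, n_boot, 2L,
                   dimnames = list(NULL, c("indirect", "kappa2")))
    n_degen <- 0L
    with_seed(split_seed(seed, "mediation-boot"), {
      b <- 1L
      while (b <= n_boot) {
        idx <- sample.int(n, n, replace = TRUE)
        xs <- x[idx]; ms <- m[idx]; ys <- y[idx]
        if (sd(xs) == 0 || sd(ms) == 0 || sd(ys) == 0) {
          n_degen <- n_degen + 1L
          if (n_degen > 0.1 * n_boot)
            stop("more than 10% of bootstrap resamples are degenerate")
          next
        }
        e <- .mediation_point(xs, ms, ys)
        boot[b, 1L] <- e[["indirect"]]
        boot[b, 2L] <- tryCatch(
          kappa_squared(e[["a"]], e[["r_my"]], e[["c"]]),
          error = function(err) NA_real_)
        b <- b + 1L
      }
    })
    if (n_degen > 0L)
      ml_log("mediate", "redrew %d degenerate resample(s)", n_degen)
    # jackknife estimates for the acceleration constant
    jack <- matrix(NA_real_, n, 2L)
    for (i in seq_len(n)) {
      e <- .mediation_point(x[-i], m[-i], y[-i])
      jack[i, 1L] <- e[["indirect"]]
      jack[i, 2L] <- tryCatch(
        kappa_squared(e[["a"]], e[["r_my"]], e[["c"]]),
        error = function(err) NA_real_)
    }
    out$ci_indirect <- .bca_ci(boot[, 1L], out$indirect, jack[, 1L], ci_level)
    out$ci_kappa2 <- .bca_ci(boot[, 2L], out$kappa2, jack[, 2L], ci_level)
    excl <- vapply(scan_levels, function(lv) {
      ci <- .bca_ci(boot[, 1L], out$indirect, jack[, 1L], lv)
      ci[1L] > 0 || ci[2L] < 0
    }, logical(1))
    out$significant <- any(excl)
    out$p_value <- if (any(excl)) min(1 - scan_levels[excl]) else NA_real_
    out$boot_mean_indirect <- mean(boot[, 1L])
  }
  structure(out, class = "mediation_result")
}

# BCa interval from bootstrap draws, the point estimate and jackknife values
.bca_ci <- function(boot, theta, jack, level) {
  boot <- boot[is.finite(boot)]
  jack <- jack[is.finite(jack)]
  alpha <- (1 - level) / 2
  prop <- mean(boot < theta)
  prop <- min(max(prop, 1 / (length(boot) + 1)), 1 - 1 / (length(boot) + 1))
  z0 <- qnorm(prop)
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  acc <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - acc * (z0 + z)))
  unname(quantile(boot, c(adj(qnorm(alpha)), adj(qnorm(1 - alpha))),
                  names = FALSE, type = 7))
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation (n = %d):\n", x$n_obs))
  cat(sprintf("  a = %.3f, b = %.3f, c = %.3f, c' = %.3f\n",
              x$a, x$b, x$c, x$c_prime))
  cat(sprintf("  indirect a*b = %.4f; kappa^2 = %.1f%%\n",
              x$indirect, 100 * x$kappa2))
  if (!is.null(x$ci_indirect)) {
    cat(sprintf("  %.1f%% BCa CI indirect: [%.4f, %.4f]; kappa^2: [%.4f, %.4f]\n",
                100 * x$ci_level, x$ci_indirect[1], x$ci_indirect[2],
                x$ci_kappa2[1], x$ci_kappa2[2]))
    cat(sprintf("  significant: %s (scan p %s)\n",
                x$significant,
                if (is.na(x$p_value)) "> 0.10" else paste0("<= ", x$p_value)))
  }
  invisible(x)
}

#' Construct a dataset realising an exact correlation triple
#'
#' Builds three n-vectors whose sample correlations equal a stated triple
#' exactly (via Gram-Schmidt on random normals followed by recolouring with
#' the Cholesky factor of the target correlation matrix). Useful for worked
#' examples where only the printed correlations are known.
#'
#' @param r_xm,r_my,r_xy target sample correlations
#' @param n sample size
#' @param seed integer seed
#' @return data.frame with columns `x`, `m`, `y`
#' @export
dataset_from_triple <- function(r_xm, r_my, r_xy, n, seed = 1L) {
  R <- matrix(c(1, r_xm, r_xy, r_xm, 1, r_my, r_xy, r_my, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("target correlation triple is not positive semi-definite")
  with_seed(split_seed(seed, "triple"), {
    Z <- matrix(rnorm(n * 3L), n, 3L)
    Z <- qr.Q(qr(cbind(1, Z)))[, 2:4] * sqrt(n - 1)  # exactly orthonormal,
    Z <- Z %*% chol(R)                               # mean-0 columns
    setNames(as.data.frame(Z), c("x", "m", "y"))
  })
}
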