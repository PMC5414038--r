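test_that("filter_cpgs applies the missing-rate rule (brute-force oracle)", {
  v <- matrix(runif(50), 10, 5,
              dimnames = list(sprintf("S%02d", 1:10), paste0("cg", 1:5)))
  v[1, 2] <- NA                     # rate 0.10 >= 0.05 -> removed
  b <- beta_matrix(v)
  kept <- suppressMessages(filter_cpgs(b, 0.05))
  expect_identical(colnames(kept$values), paste0("cg", c(1, 3:5)))
  # vacuous threshold
  expect_identical(colnames(filter_cpgs(b, 1)$values), paste0("cg", 1:5))
  # toy 5x4 with a scattered pattern vs exhaustive per-column count
  set.seed(42)
  w <- matrix(runif(20), 5, 4, dimnames = list(NULL, paste0("cg", 1:4)))
  w[sample(20, 6)] <- NA
  thr <- 0.4
  oracle_keep <- vapply(1:4, function(j) mean(is.na(w[, j])) < thr,
                        logical(1))
  got <- suppressMessages(filter_cpgs(beta_matrix(w), thr))
  expect_identical(colnames(got$values), paste0("cg", 1:4)[oracle_keep])
  expect_error(filter_cpgs(beta_matrix(matrix(NA_real_, 3, 1,
                                              dimnames = list(NULL, "cg1"))),
                           0.05),
               "all CpGs removed")
})

test_that("impute_knn matches exhaustive nearest-neighbour search", {
  v <- matrix(runif(40), 8, 5, dimnames = list(paste0("S", 1:8),
                                               paste0("cg", 1:5)))
  b <- beta_matrix(v)
  expect_identical(impute_knn(b)$values, v)   # no missing -> identity
  # single missing entry, k = 1: equals the value of the nearest sample by
  # Euclidean distance over the shared (observed) CpGs
  v2 <- v; v2[3, 2] <- NA
  got <- impute_knn(beta_matrix(v2), k = 1L)
  d <- apply(v[-3, -2, drop = FALSE], 1L,
             function(r) sqrt(sum((r - v[3, -2])^2)))
  nearest <- rownames(v)[-3][which.min(d)]
  expect_equal(got$values[3, 2], v[nearest, 2])
  expect_identical(got$values[-3, ], v[-3, ])  # observed untouched
  # identical donors -> imputed value is that constant
  v3 <- matrix(0.4, 6, 3, dimnames = list(NULL, paste0("cg", 1:3)))
  v3[, 3] <- runif(6); v3[2, 1] <- NA
  expect_equal(impute_knn(beta_matrix(v3), k = 3L)$values[2, 1], 0.4)
  # entirely missing CpG is an error
  v4 <- v; v4[, 5] <- NA
  expect_error(impute_knn(beta_matrix(v4)), "no observed values")
})

test_that("estimate_svs: null data give 0, planted batch is recovered", {
  set.seed(1)
  n <- 200; p <- 1000
  age <- runif(n, 18, 35)
  sex <- rbinom(n, 1, 0.5)
  noise <- matrix(rnorm(n * p, 0.5, 0.05), n, p)
  noise[] <- pmin(pmax(noise, 0), 1)
  colnames(noise) <- paste0("cg", 1:p)
  # pure known-covariate signal + iid noise -> "auto" finds nothing
  v <- plogis(qlogis(noise) + 0.3 * sex)
  colnames(v) <- paste0("cg", 1:p)
  sv0 <- suppressMessages(estimate_svs(v, protected = age,
                                       known = data.frame(sex = sex)))
  expect_identical(ncol(sv0), 0L)
  # one large planted batch factor -> first surrogate tracks it
  batch <- rbinom(n, 1, 0.5)
  eff <- matrix(0, n, p)
  idx <- sample(p, 200)
  eff[, idx] <- outer(batch - mean(batch), rnorm(200, 0, 2))
  v2 <- plogis(qlogis(noise) + eff)
  sv <- suppressMessages(estimate_svs(v2, protected = age,
                                      known = data.frame(sex = sex),
                                      n_sv = 1L))
  expect_gt(abs(cor(sv$sv1, batch)), 0.9)
  # surrogates are orthogonal to the protected covariate by construction
  expect_lt(abs(cor(sv$sv1, age)), 1e-8)
  # zero surrogates leave downstream residualization unchanged
  r1 <- residualize(v2, data.frame(sex = sex))
  r2 <- residualize(v2, cbind(data.frame(sex = sex), sv0))
  expect_equal(r1$values, r2$values)
  expect_error(estimate_svs(v, protected = age, n_sv = 199L), "n_sv")
})

test_that("residualize: OLS oracle, degenerate CpGs, invariants", {
  # intercept-only adjustment is plain z-scoring
  v <- matrix(runif(60, 0.2, 0.8), 10, 6,
              dimnames = list(NULL, paste0("cg", 1:6)))
  r0 <- residualize(v)
  zs <- apply(v, 2L, function(cc) (cc - mean(cc)) / sd(cc))
  expect_equal(r0$values, zs)
  # 6x2 toy vs hand-computed normal-equations residuals
  z <- c(1.2, 0.5, -0.3, 2.0, 1.1, -0.7)
  y <- matrix(c(0.2, 0.4, 0.3, 0.8, 0.5, 0.1,
                0.9, 0.2, 0.6, 0.4, 0.3, 0.7), 6, 2,
              dimnames = list(NULL, c("cgA", "cgB")))
  X <- cbind(1, z)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  oracle <- y - X %*% beta_hat
  got <- residualize(y, data.frame(z = z))
  expect_equal(got$values, apply(oracle, 2L, function(cc) cc / sd(cc)),
               tolerance = 1e-12)
  # CpG exactly linear in the covariate is dropped with a warning
  sex <- rep(c(0, 1), 5)
  v2 <- cbind(v, cgSex = 0.2 + 0.3 * sex)
  expect_warning(r2 <- residualize(v2, data.frame(sex = sex)),
                 "zero residual variance")
  expect_false("cgSex" %in% colnames(r2$values))
  # rank-deficient design errors with the column named
  expect_error(residualize(y, data.frame(a = z, b = 2 * z)), "collinear")
})

test_that("residualize is idempotent and orthogonal to covariates", {
  set.seed(3)
  n <- 50
  covs <- data.frame(age = runif(n, 18, 35), sex = rbinom(n, 1, 0.5))
  v <- matrix(runif(n * 20, 0.1, 0.9), n, 20,
              dimnames = list(NULL, paste0("cg", 1:20)))
  r1 <- residualize(v, covs)
  r2 <- residualize(r1, covs)
  expect_lt(max(abs(r1$values - r2$values)), 1e-10)
  ortho <- abs(cor(r1$values, data.matrix(covs)))
  expect_lt(max(ortho), 1e-8)
})
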