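fake_model <- function(loadings_row, cpg_ids = NULL) {
  S <- matrix(loadings_row, nrow = 1)
  colnames(S) <- cpg_ids %||% paste0("cg", seq_along(loadings_row))
  rownames(S) <- "IC1"
  structure(list(S = S, A = matrix(rnorm(10), 10, 1), k = 1L,
                 stability = 1, dominance = 0.05, retained = TRUE),
            class = "ica_model")
}

test_that("signature selection: tail counts, small-n arithmetic,
           affine equivariance", {
  # gaussian loadings: selected count sits in the Poisson band implied by
  # the 4-sigma two-sided tail
  set.seed(13)
  p <- 100000
  s <- rnorm(p)
  sig <- select_signature(fake_model(s), "IC1", n_sigma = 4)
  lambda <- p * 2 * pnorm(-4)
  band <- qpois(c(0.005, 0.995), lambda)
  expect_gte(length(sig$cpg_ids), band[1])
  expect_lte(length(sig$cpg_ids), band[2])
  # [0,0,0,10]: sample sd 5, mean 2.5 -> |10 - 2.5| < 4*5 -> empty set
  sig2 <- select_signature(fake_model(c(0, 0, 0, 10)), 1, n_sigma = 4)
  expect_length(sig2$cpg_ids, 0)
  # affine rescaling of the loadings row selects the same set
  sig_a <- select_signature(fake_model(3 * s + 7), 1, n_sigma = 4)
  expect_identical(sig_a$cpg_ids, sig$cpg_ids)
  expect_identical(sig_a$direction, sig$direction)
})

test_that("planted active CpGs are recovered at high loading scale", {
  d <- clean_design(n = 200, p = 5000, k = 3, seed = 15, loading_scale = 6)
  co <- generate_methylome(d)
  model <- decompose_methylome(residualize(co$betas), k = 3,
                               n_restarts = 5, seed = 2)
  # match each estimated component to its planted counterpart
  cc <- abs(cor(model$A, co$truth$A))
  for (true_j in 1:3) {
    est_j <- which.max(cc[, true_j])
    sig <- select_signature(model, est_j, n_sigma = 4)
    planted <- colnames(co$betas$values)[co$truth$active[[true_j]]]
    recall <- mean(planted %in% sig$cpg_ids)
    expect_gte(recall, 0.9)
  }
})

test_that("context classification follows the precedence rules and the
           exhaustive interval-scan oracle", {
  tx <- data.frame(gene_id = c("G1", "G2"), transcript_id = c("T1", "T2"),
                   chrom = "chr1", start = c(10000, 30000),
                   end = c(20000, 40000), strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  cp <- data.frame(
    cpg_id = paste0("cg", 1:5), chrom = "chr1",
    pos = c(9000,    # 1,000 bp 5' of the + strand TSS -> TSS
            15000,   # inside T1 -> Genic
            41000,   # 1,000 bp 5' of the - strand TSS (end+1000) -> TSS
            25000,   # between transcripts -> Intergenic
            19000),  # inside T1 AND 1,200 bp upstream... see below
    stringsAsFactors = FALSE)
  got <- classify_cpg_context(cp, tx)
  expect_identical(as.character(got$context),
                   c("TSS", "Genic", "TSS", "Intergenic", "Genic"))
  # precedence: a CpG in one transcript body but upstream of another TSS
  tx2 <- rbind(tx, data.frame(gene_id = "G3", transcript_id = "T3",
                              chrom = "chr1", start = 16200, end = 17000,
                              strand = "+", stringsAsFactors = FALSE))
  got2 <- classify_cpg_context(data.frame(cpg_id = "cgX", chrom = "chr1",
                                          pos = 15000), tx2)
  expect_identical(as.character(got2$context), "TSS")
  # 50 random CpGs vs 5 random transcripts: brute-force oracle agreement
  set.seed(31)
  tx3 <- data.frame(gene_id = paste0("G", 1:5),
                    transcript_id = paste0("T", 1:5),
                    chrom = sample(c("chr1", "chr2"), 5, TRUE),
                    start = sample(1e4:5e5, 5), stringsAsFactors = FALSE)
  tx3$end <- tx3$start + sample(2000:50000, 5)
  tx3$strand <- sample(c("+", "-"), 5, TRUE)
  cp3 <- data.frame(cpg_id = paste0("cg", 1:50),
                    chrom = sample(c("chr1", "chr2"), 50, TRUE),
                    pos = sample(1e4:6e5, 50), stringsAsFactors = FALSE)
  got3 <- classify_cpg_context(cp3, tx3)
  expect_identical(as.character(got3$context), oracle_context(cp3, tx3))
  # unknown chromosome -> Intergenic with warning
  expect_warning(
    got4 <- classify_cpg_context(
      data.frame(cpg_id = "cgY", chrom = "chrZ", pos = 100), tx),
    "absent")
  expect_identical(as.character(got4$context), "Intergenic")
})

test_that("context chi-squared: closed forms and null calibration", {
  # all-one-category signature vs uniform 4-category background: chi2 = 3n
  n <- 40
  sig <- setNames(c(n, 0, 0, 0), c("A", "B", "C", "D"))
  bg <- setNames(rep(1000, 4), c("A", "B", "C", "D"))
  got <- suppressWarnings(context_chisq(sig, bg))
  expect_equal(got$chi2, 3 * n)
  expect_equal(got$df, 3L)
  # identical proportions: chi2 = 0, p = 1
  same <- context_chisq(setNames(c(10, 20, 30), c("A", "B", "C")),
                        setNames(c(100, 200, 300), c("A", "B", "C")))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # signatures drawn from the background give uniform p (KS check)
  set.seed(17)
  probs <- c(0.2, 0.3, 0.4, 0.1)
  pv <- replicate(2000, {
    draw <- as.vector(rmultinom(1, 120, probs))
    suppressWarnings(context_chisq(
      setNames(draw, c("A", "B", "C", "D")),
      setNames(round(probs * 1e5), c("A", "B", "C", "D"))))$p
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("projection: round trip, alignment invariance, replication", {
  fx <- decomposed_fixture()
  pr <- project_component(fx$model, "IC1", fx$cohort$betas)
  expect_gt(abs(cor(pr$weights, fx$model$A[, "IC1"])), 0.999)
  # permuting CpG columns leaves the projection unchanged
  v <- fx$cohort$betas$values
  perm <- sample(ncol(v))
  pr_p <- project_component(fx$model, "IC1", beta_matrix(v[, perm]))
  expect_equal(pr_p$weights, pr$weights, tolerance = 1e-10)
  # an independent cohort from the same truth is recovered
  rep2 <- replicate_methylome(fx$cohort$truth, 250, seed = 42)
  for (true_j in 1:3) {
    est_j <- which.max(abs(cor(fx$model$A, fx$cohort$truth$A[, true_j])))
    prj <- project_component(fx$model, est_j, rep2$betas)
    expect_gt(abs(cor(prj$weights, rep2$truth$A[, true_j])), 0.9)
  }
  # single-component mode agrees with the full inverse up to sign at high
  # SNR (same subspace), and the overlap guard trips
  pr_s <- project_component(fx$model, "IC1", fx$cohort$betas,
                            method = "single")
  expect_gt(abs(cor(pr_s$weights, pr$weights)), 0.95)
  few <- beta_matrix(v[, 1:100])
  expect_error(project_component(fx$model, "IC1", few), "90")
})

test_that("overlap odds ratios and hypergeometric tails", {
  # direct arithmetic: table (a=10, b=5, c=5, d=980)
  A <- c(paste0("s", 1:10), paste0("a", 1:5))
  B <- c(paste0("s", 1:10), paste0("b", 1:5))
  got <- overlap_or(A, B, universe = 1000)
  expect_equal(got$odds_ratio, (10 * 980) / (5 * 5))
  expect_equal(got$p, oracle_hyper_upper(10, 15, 985, 15), tolerance = 1e-12)
  # identical sets: infinite OR with finite Haldane estimate alongside
  ident <- overlap_or(A, A, universe = 1000)
  expect_identical(ident$odds_ratio, Inf)
  expect_true(is.finite(ident$odds_ratio_haldane))
  expect_error(overlap_or(character(0), B, 100), "empty")
  # independent random sets have median OR near 1
  set.seed(23)
  ors <- replicate(200, {
    u <- paste0("g", 1:400)
    overlap_or(sample(u, 100), sample(u, 100), 400)$odds_ratio_haldane
  })
  expect_lt(abs(median(ors) - 1), 0.25)
})
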