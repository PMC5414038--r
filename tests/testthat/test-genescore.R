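test_that("HWE exact test matches direct factorial enumeration", {
  # independent oracle: enumerate admissible heterozygote counts with
  # choose()-based conditional probabilities
  oracle_hwe <- function(het, rare_hom, com_hom) {
    n <- het + rare_hom + com_hom
    nr <- 2 * rare_hom + het
    if (nr > n) nr <- 2 * n - nr
    hets <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
    pr <- vapply(hets, function(h) {
      ra <- (nr - h) / 2; co <- n - h - ra
      factorial(n) / (factorial(h) * factorial(ra) * factorial(co)) *
        2^h * factorial(nr) * factorial(2 * n - nr) / factorial(2 * n)
    }, numeric(1))
    sum(pr[pr <= pr[match(het, hets)] + 1e-12])
  }
  cases <- list(c(5, 2, 3), c(0, 5, 5), c(8, 1, 1), c(4, 0, 6))
  for (cs in cases)
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 oracle_hwe(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  # 100/0/100 with no heterozygotes is grossly out of equilibrium
  expect_lt(hwe_exact_p(0, 100, 100), 1e-4)
})

test_that("snp_qc applies MAF, HWE and call-rate rules", {
  set.seed(14)
  n <- 100
  good <- rbinom(n, 2, 0.3)
  mono <- rep(0L, n)                         # MAF 0
  no_het <- c(rep(0L, 50), rep(2L, 50))      # HWE failure
  sparse <- good; sparse[1:8] <- NA          # call rate 0.92
  counts <- cbind(snp_good = good, snp_mono = mono, snp_nohet = no_het,
                  snp_sparse = sparse)
  qc <- suppressMessages(snp_qc(counts))
  expect_setequal(colnames(qc$counts), c("snp_good", "snp_sparse"))
  qc95 <- suppressMessages(snp_qc(counts, callrate_min = 0.95))
  expect_setequal(colnames(qc95$counts), "snp_good")
  expect_error(suppressMessages(snp_qc(cbind(a = mono))), "no SNP")
})

test_that("build_gene_score: selection rules, weights, arithmetic", {
  set.seed(16)
  n <- 300
  g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.4)
  g3 <- rbinom(n, 2, 0.25); g4 <- rbinom(n, 2, 0.35)
  w <- 0.5 * g1 - 0.5 * g2 + 0.15 * g3 + rnorm(n, 0, 0.8)
  counts <- cbind(rsA = g1, rsB = g2, rsC = g3, rsD = g4)
  map <- data.frame(snp_id = c("rsA", "rsB", "rsC", "rsD"),
                    gene = c("G1", "G2", "G3", "G4"))
  gs <- build_gene_score(counts, w, map)
  # direction weights follow the sign of the minor-allele effect
  expect_identical(unname(gs$weights[c("rsA", "rsB")]), c(1, -1))
  expect_gt(cor(gs$score, w), 0)
  # all-positive weights, no missing data: score is the centred row sum
  wpos <- 0.5 * g1 + 0.5 * g2 + rnorm(n, 0, 0.3)
  gs2 <- build_gene_score(counts[, 1:2], wpos, map[1:2, ])
  raw <- g1 + g2
  expect_equal(unname(gs2$score), raw - mean(raw), tolerance = 1e-12)
  # one most significant SNP per gene, tie broken lexicographically
  map2 <- data.frame(snp_id = c("rsA", "rsB"), gene = c("GX", "GX"))
  gsx <- build_gene_score(counts[, 1:2], w, map2)
  expect_length(gsx$snps, 1L)
  pA <- summary(lm(w ~ g1))$coefficients[2, 4]
  pB <- summary(lm(w ~ g2))$coefficients[2, 4]
  expect_identical(gsx$snps, c("rsA", "rsB")[which.min(c(pA, pB))])
  # exact tie within one gene: lexicographic SNP-ID tie-break
  tie_counts <- cbind(rsZ = g1, rsY = g1)
  gst <- build_gene_score(tie_counts, w,
                          data.frame(snp_id = c("rsZ", "rsY"),
                                     gene = c("GX", "GX")))
  expect_identical(gst$snps, "rsY")
  # a SNP serving two set genes keeps only one gene
  gsd <- build_gene_score(cbind(rsA = g1), w,
                          data.frame(snp_id = c("rsA", "rsA"),
                                     gene = c("GA", "GB")))
  expect_length(gsd$snps, 1L)
  expect_length(gsd$genes, 1L)
  # no qualifying SNP errors
  expect_error(build_gene_score(counts, rnorm(n), map,
                                p_threshold = 1e-12), "qualifying")
  # score invariant to SNP column order
  gs_perm <- build_gene_score(counts[, c(3, 1, 4, 2)], w, map)
  expect_equal(sort(gs_perm$snps), sort(gs$snps))
  expect_equal(gs_perm$score, gs$score)
})

test_that("planted mQTL world yields a working score", {
  g <- genetic_fixture()
  qc <- suppressMessages(snp_qc(g$genotypes$counts))
  gs <- suppressMessages(build_gene_score(qc$counts, g$w, g$genotypes$map))
  expect_gt(cor(gs$score, g$w), 0.3)
  # selected SNPs are strongly enriched for the planted causal set
  causal <- g$genotypes$map$snp_id[g$genotypes$map$causal]
  expect_gt(mean(gs$snps %in% causal), 0.5)
})

test_that("one-sided score tests are exact and calibrated", {
  # orthogonal toy: r = 0 exactly -> one-sided p = 0.5
  x <- c(1, -1, 1, -1); y <- c(1, 1, -1, -1)
  expect_equal(score_cor_test(x, y, sidedness = "less")$p_nominal, 0.5)
  # negative correlation -> lower-tail p < 0.5
  expect_lt(score_cor_test(c(1, 2, 3, 4), c(4, 3.5, 2, 1),
                           sidedness = "less")$p_nominal, 0.5)
  # type-I calibration of the lower-tail test on null data
  set.seed(25)
  n <- 200; reps <- 5000
  X <- matrix(rnorm(n * reps), n); Y <- matrix(rnorm(n * reps), n)
  r <- colSums(scale(X) * scale(Y)) / (n - 1)
  p <- pt(r * sqrt((n - 2) / (1 - r^2)), n - 2)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
  expect_equal(score_cor_test(X[, 7], Y[, 7], sidedness = "less")$p_nominal,
               p[7], tolerance = 1e-10)
})

test_that("Stouffer meta-analysis: identities and hand-computed cases", {
  # single study returns its own p (weights cancel)
  one <- stouffer_meta(r = -0.1, n = 500, p = 0.031)
  expect_equal(one$combined_p, 0.031, tolerance = 1e-12)
  # k identical studies: Z scales by sqrt(k)
  k <- 4
  many <- stouffer_meta(rep(-0.1, k), rep(500, k), rep(0.05, k))
  expect_equal(many$combined_z, sqrt(k) * qnorm(0.95), tolerance = 1e-10)
  # two studies, equal n, p = 0.05 each: hand-computed combination
  two <- stouffer_meta(c(-0.1, -0.1), c(300, 300), c(0.05, 0.05))
  expect_equal(two$combined_p, 1 - pnorm(2 * qnorm(0.95) / sqrt(2)),
               tolerance = 1e-12)
  # weighting variants
  wn <- stouffer_meta(c(-0.1, -0.2), c(100, 400), c(0.05, 0.2),
                      weights = "n")
  expect_equal(wn$combined_z,
               (100 * qnorm(0.95) + 400 * qnorm(0.8)) / sqrt(100^2 + 400^2),
               tolerance = 1e-10)
  # weighted mean r uses n-weights
  expect_equal(wn$weighted_r, (100 * -0.1 + 400 * -0.2) / 500)
  expect_warning(stouffer_meta(c(0, 0), c(10, 10), c(0, 0.5)), "clipped")
})

test_that("cis enrichment matches the geometric oracle on a toy genome", {
  genome <- c(chr1 = 1e7)
  cpg <- data.frame(chrom = "chr1", pos = 5e6)
  # all SNPs on the CpG position: fraction 1, minimal p
  snps_on <- data.frame(chrom = rep("chr1", 10), pos = rep(5e6, 10))
  ce <- cis_enrichment(snps_on, cpg, genome, window = 1e6, n_perm = 500,
                       seed = 2)
  expect_equal(ce$observed_fraction, 1)
  # null fraction approximates the window coverage 2e6/1e7 = 0.2
  expect_lt(abs(ce$null_mean - 0.2), 0.02)
  expect_equal(ce$p, 1 / 501, tolerance = 0.2)
  # saturated genome: everything is cis, p ~ 1
  cpg_all <- data.frame(chrom = "chr1", pos = seq(5e5, 9.5e6, by = 5e5))
  snps_any <- data.frame(chrom = rep("chr1", 10),
                         pos = round(seq(1e5, 9.9e6, length.out = 10)))
  ce2 <- cis_enrichment(snps_any, cpg_all, genome, window = 1e6,
                        n_perm = 300, seed = 3)
  expect_equal(ce2$observed_fraction, 1)
  expect_gt(ce2$p, 0.99)
})

test_that("mQTL pair tests: null calibration and planted signal", {
  set.seed(27)
  n <- 300; m <- 100
  counts <- matrix(rbinom(n * m, 2, 0.3), n, m,
                   dimnames = list(NULL, paste0("rs", 1:m)))
  null_res <- matrix(rnorm(n * m), n, m,
                     dimnames = list(NULL, paste0("cg", 1:m)))
  pairs <- data.frame(snp_id = paste0("rs", 1:m),
                      cpg_id = paste0("cg", 1:m))
  mq0 <- mqtl_tests(counts, null_res, pairs)
  expect_gt(mq0$ks_p, 0.01)
  # planted effects shift the p distribution left
  eff_res <- 0.3 * counts + matrix(rnorm(n * m), n, m)
  colnames(eff_res) <- paste0("cg", 1:m)
  mq1 <- mqtl_tests(counts, eff_res, pairs)
  expect_lt(mq1$ks_p, 0.01)
  expect_gt(mean(mq1$results$p < 0.05), mean(mq0$results$p < 0.05))
  # a perfect linear pair hits the machine floor
  perfect <- counts[, 1, drop = FALSE] * 0.5
  colnames(perfect) <- "cgP"
  mqp <- mqtl_tests(counts, perfect,
                    data.frame(snp_id = "rs1", cpg_id = "cgP"))
  expect_lt(mqp$results$p, 1e-200)
  # monomorphic SNP skipped with warning
  counts2 <- cbind(counts, rsMono = rep(1L, n))
  expect_warning(
    mqtl_tests(counts2, null_res,
               data.frame(snp_id = c("rs1", "rsMono"),
                          cpg_id = c("cg1", "cg2"))),
    "monomorphic")
})
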