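test_that("Wallenius reduces to the central hypergeometric at odds 1", {
  # uniform bias -> one weight bin -> odds exactly 1 -> Fisher agreement
  cases <- list(c(m1 = 50, m2 = 450, n = 60, x = 15),
                c(m1 = 20, m2 = 80, n = 30, x = 10),
                c(m1 = 100, m2 = 900, n = 50, x = 3))
  for (cs in cases) {
    pw <- pwallenius_upper(cs["x"], cs["m1"], cs["m2"], cs["n"], w = 1)
    pf_ <- phyper(cs["x"] - 1, cs["m1"], cs["m2"], cs["n"],
                  lower.tail = FALSE)
    expect_lt(abs(pw - pf_), 1e-6)
  }
  universe <- paste0("G", 1:500)
  bias <- setNames(rep(3, 500), universe)
  sel <- paste0("G", 1:60)
  sets <- list(hit = paste0("G", c(1:20, 400:429)),
               null = paste0("G", 201:260))
  ew <- enrich_wallenius(sel, bias, sets)
  for (id in ew$set_id) {
    row <- ew[ew$set_id == id, ]
    expect_lt(abs(row$p - phyper(row$n_selected_in_set - 1,
                                 row$n_genes_in_set,
                                 500 - row$n_genes_in_set, 60,
                                 lower.tail = FALSE)), 1e-6)
  }
})

test_that("Wallenius tail equals exhaustive enumeration on a tiny universe", {
  # 12 genes: 5 in the set with odds w, 7 outside; 5 draws
  for (w in c(0.5, 1, 2.5)) {
    pmf_oracle <- oracle_wallenius_pmf(5, 7, 5, w)
    for (x in 0:5) {
      expect_lt(abs(dwallenius(x, 5, 7, 5, w) - pmf_oracle[x + 1]), 1e-6)
      expect_lt(abs(pwallenius_upper(x, 5, 7, 5, w) -
                      sum(pmf_oracle[(x + 1):6])), 1e-6)
    }
  }
  # degenerate draw-everything case
  expect_equal(dwallenius(5, 5, 7, 12, 2), 1)
})

test_that("bias correction weakens enrichment of high-bias sets", {
  # selection probability strictly increasing in bias; the "enriched" set
  # is made of high-bias genes, so Wallenius must discount it vs Fisher
  set.seed(33)
  n_genes <- 2000
  bias <- setNames(sample(1:40, n_genes, replace = TRUE),
                   paste0("G", 1:n_genes))
  p_sel <- bias / max(bias)
  selected <- names(bias)[runif(n_genes) < p_sel * 0.4]
  high_bias_set <- names(sort(bias, decreasing = TRUE))[1:100]
  sets <- list(high = high_bias_set)
  ew <- suppressWarnings(enrich_wallenius(selected, bias, sets))
  x <- ew$n_selected_in_set[1]
  fisher_p <- phyper(x - 1, 100, n_genes - 100, length(selected),
                     lower.tail = FALSE)
  expect_gt(ew$p[1], fisher_p)
  expect_gt(ew$odds[1], 1)
  # empty-intersection sets are skipped with a warning
  expect_warning(enrich_wallenius(selected, bias,
                                  list(x = "NOPE", ok = high_bias_set)),
                 "skipped")
})

test_that("BH FDR matches the step-up definition on enumerable lists", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.9)
  m <- length(p)
  stepup <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(sort(p))]
  # route through the enrichment result to test our attached column
  bias <- setNames(rep(2, 200), paste0("G", 1:200))
  sel <- paste0("G", 1:40)
  sets <- lapply(1:10, function(i) paste0("G", sample(200, 30)))
  names(sets) <- paste0("S", 1:10)
  set.seed(1)
  ew <- enrich_wallenius(sel, bias, sets)
  expect_equal(ew$fdr, p.adjust(ew$p, "BH"))
  expect_equal(sort(p.adjust(p, "BH")), sort(pmin(stepup, 1)))
})

test_that("percentile GSEA: extreme set, null calibration, confounders", {
  set.seed(35)
  n_genes <- 1500
  gene_p <- setNames(runif(n_genes), paste0("G", 1:n_genes))
  # a set made of top-quartile genes only sits at the permutation floor
  top <- names(sort(gene_p))[1:40]
  res_top <- enrich_percentile_gsea(gene_p, list(top = top),
                                    n_perm = 1000, seed = 2)
  expect_equal(res_top$p, 1 / 1001)
  # null: random sets of varying size give uniform p-values
  sizes <- sample(20:200, 80, replace = TRUE)
  sets <- lapply(sizes, function(s) paste0("G", sample(n_genes, s)))
  names(sets) <- paste0("S", seq_along(sets))
  res <- enrich_percentile_gsea(gene_p, sets, n_perm = 2000, seed = 3)
  expect_gt(suppressWarnings(ks.test(res$p, "punif"))$p.value, 0.01)
  # sets outside the size bounds are skipped
  small <- list(tiny = paste0("G", 1:5))
  expect_error(enrich_percentile_gsea(gene_p, small, n_perm = 100,
                                      seed = 1), "size bounds")
  # confounder fully explaining the scores: a confounder-aligned set is
  # null after adjustment in most replicates
  hits <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    conf <- rnorm(n_genes)
    score <- 5 + 0.8 * conf + 0.3 * rnorm(n_genes)  # strictly linear in conf
    gp <- setNames(pmin(10^(-score), 1), paste0("G", 1:n_genes))
    aligned <- paste0("G", order(-conf)[1:60])
    res_c <- enrich_percentile_gsea(gp, list(a = aligned),
                                    confounders = data.frame(conf = conf),
                                    n_perm = 500, seed = s)
    if (res_c$p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("best-SNP gene scores take the per-gene minimum", {
  snp_p <- c(rs1 = 0.2, rs2 = 0.01, rs3 = 0.5, rs4 = 0.03)
  map <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                    gene = c("A", "A", "B", "B"))
  got <- best_snp_gene_p(snp_p, map)
  expect_equal(unname(got["A"]), 0.01)
  expect_equal(unname(got["B"]), 0.03)
})
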