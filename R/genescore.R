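
#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact (conditional on allele counts) test enumerating heterozygote
#' counts, preferred over the chi-squared approximation at desk-scale
#' sample sizes.
#'
#' @param n_het,n_hom_rare,n_hom_common genotype counts
#' @return two-sided exact p-value
#' @export
hwe_exact_p <- function(n_het, n_hom_rare, n_hom_common) {
  stopifnot(n_het >= 0, n_hom_rare >= 0, n_hom_common >= 0)
  n <- n_het + n_hom_rare + n_hom_common
  if (n == 0L) return(1)
  n_rare <- 2L * n_hom_rare + n_het
  if (n_rare > n) { # ensure "rare" really is the minor allele
    n_rare <- 2L * n - n_rare
    tmp <- n_hom_rare; n_hom_rare <- n_hom_common; n_hom_common <- tmp
  }
  hets <- seq.int(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  # log-probabilities of each admissible heterozygote count
  lp <- vapply(hets, function(h) {
    ra <- (n_rare - h) / 2
    co <- n - h - ra
    lgamma(n + 1) - lgamma(h + 1) - lgamma(ra + 1) - lgamma(co + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' SNP quality control
#'
#' Removes SNPs failing minor-allele-frequency, Hardy-Weinberg (exact
#' test) or call-rate thresholds. Defaults mirror common array QC:
#' MAF >= 0.01, HWE exact p > 1e-4, call rate >= 0.90.
#'
#' @param counts sample x SNP minor-allele count matrix (`0/1/2/NA`)
#' @param maf_min minimum minor allele frequency
#' @param hwe_p_min SNPs with exact HWE p-value at or below this are removed
#' @param callrate_min minimum per-SNP call rate
#' @return list `counts` (filtered matrix) and `stats` (per-SNP maf, hwe_p,
#'   callrate, kept flag for the input SNPs)
#' @export
snp_qc <- function(counts, maf_min = 0.01, hwe_p_min = 1e-4,
                   callrate_min = 0.90) {
  stopifnot(is.matrix(counts))
  callrate <- colMeans(!is.na(counts))
  f <- colMeans(counts, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(ncol(counts)), function(j) {
    g <- counts[, j]; g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_p(sum(g == 1L), sum(g == 2L), sum(g == 0L))
  }, numeric(1))
  keep <- maf >= maf_min & hwe > hwe_p_min & callrate >= callrate_min
  if (!any(keep)) stop("no SNP survives quality control")
  ml_log("genescore", "snp_qc: %d of %d SNPs retained",
         sum(keep), ncol(counts))
  list(counts = counts[, keep, drop = FALSE],
       stats = data.frame(snp_id = colnames(counts), maf = maf, hwe_p = hwe,
                          callrate = callrate, kept = keep,
                          stringsAsFactors = FALSE))
}

# per-SNP additive association of a numeric outcome with allele counts;
# returns beta, r and two-sided p per SNP (NA pairs dropped)
.snp_assoc <- function(counts, outcome) {
  vapply(seq_len(ncol(counts)), function(j) {
    g <- counts[, j]
    ok <- !is.na(g) & !is.na(outcome)
    g <- g[ok]; yy <- outcome[ok]
    if (length(g) < 3L || sd(g) == 0 || sd(yy) == 0)
      return(c(beta = NA_real_, r = NA_real_, p = NA_real_))
    r <- cor(g, yy)
    tt <- r * sqrt((length(g) - 2) / max(1 - r^2, .Machine$double.xmin))
    c(beta = r * sd(yy) / sd(g), r = r,
      p = 2 * pt(-abs(tt), df = length(g) - 2))
  }, c(beta = 0, r = 0, p = 0))
}

#' Build a direction-weighted multilocus genetic score
#'
#' Associates each SNP additively with the component pattern, keeps within
#' each gene of `gene_set` the most significant SNP provided its nominal
#' p-value is below `p_threshold` (ties broken lexicographically by SNP
#' ID), prunes SNPs mapping to multiple set genes to the gene with the
#' stronger signal, weights each selected SNP by the sign (+1/-1) of its
#' minor-allele effect, sums `weight * count` over non-missing SNPs per
#' sample, and residualizes the resulting score on the per-sample count of
#' missing score SNPs. The weighting guarantees a non-negative training
#' correlation of the score with the component in expectation.
#'
#' @param counts sample x SNP minor-allele count matrix (post-QC)
#' @param component per-sample component weights (e.g. age-adjusted), or a
#'   `component_pattern`
#' @param gene_map data.frame `snp_id`, `gene`
#' @param gene_set character vector of gene IDs forming the score set
#'   (default: all mapped genes)
#' @param p_threshold per-SNP selection threshold (default 0.05)
#' @return a `gene_score_model`: selected `snps`, `genes`, `weights`,
#'   selection `p`, `score` (missingness-adjusted per-sample score) and
#'   `missing_count`
#' @export
build_gene_score <- function(counts, component, gene_map, gene_set = NULL,
                             p_threshold = 0.05) {
  w <- if (inherits(component, "component_pattern")) component$weights
       else component
  stopifnot(is.matrix(counts), length(w) == nrow(counts))
  if (is.null(gene_set)) gene_set <- unique(gene_map$gene)
  map <- gene_map[gene_map$gene %in% gene_set &
                    gene_map$snp_id %in% colnames(counts), , drop = FALSE]
  if (!nrow(map)) stop("no qualifying SNP in any gene of the set")
  assoc <- .snp_assoc(counts[, unique(map$snp_id), drop = FALSE], w)
  stats <- data.frame(snp_id = unique(map$snp_id),
                      beta = assoc["beta", ], p = assoc["p", ],
                      stringsAsFactors = FALSE)
  map <- merge(map, stats, by = "snp_id")
  map <- map[!is.na(map$p) & map$p < p_threshold, , drop = FALSE]
  if (!nrow(map)) stop("no qualifying SNP in any gene of the set")
  # one most significant SNP per gene; ties broken by SNP ID
  map <- map[order(map$gene, map$p, map$snp_id), , drop = FALSE]
  sel <- map[!duplicated(map$gene), , drop = FALSE]
  # proximity pruning: a SNP serving several set genes keeps only the gene
  # with the stronger (smaller-p) signal
  sel <- sel[order(sel$snp_id, sel$p, sel$gene), , drop = FALSE]
  sel <- sel[!duplicated(sel$snp_id), , drop = FALSE]
  weights <- setNames(ifelse(sel$beta >= 0, 1, -1), sel$snp_id)
  G <- counts[, sel$snp_id, drop = FALSE]
  contrib <- sweep(G, 2L, weights, `*`)
  raw <- rowSums(contrib, na.rm = TRUE)
  missing_count <- rowSums(is.na(G))
  score <- if (sd(missing_count) > 0)
    partial_out(raw, data.frame(missing = missing_count))
  else raw - mean(raw)
  structure(list(snps = sel$snp_id, genes = sel$gene,
                 weights = weights,
                 selection_p = setNames(sel$p, sel$snp_id),
                 selection_p_threshold = p_threshold,
                 score = setNames(score, rownames(counts)),
                 missing_count = missing_count),
            class = "gene_score_model")
}

#' @export
print.gene_score_model <- function(x, ...) {
  cat(sprintf("gene_score_model: %d SNPs (one per gene; %d+, %d-), p < %g\n",
              length(x$snps), sum(x$weights > 0), sum(x$weights < 0),
              x$selection_p_threshold))
  invisible(x)
}

#' Test a genetic score against a phenotype
#'
#' Pearson correlation with a declared sidedness: memory-performance tests
#' use the lower tail (the score is built to correlate positively with the
#' pattern, which correlates negatively with memory).
#'
#' @param model a `gene_score_model` (or numeric score vector)
#' @param phenotype aligned numeric vector
#' @param sidedness `"less"`, `"greater"` or `"two"`
#' @param n_tests Bonferroni family size
#' @return an `assoc_result`
#' @export
score_cor_test <- function(model, phenotype, sidedness = "less",
                           n_tests = 1L) {
  s <- if (inherits(model, "gene_score_model")) model$score else model
  assoc_cor(s, phenotype, sidedness = sidedness, n_tests = n_tests)
}

#' Stouffer meta-analysis of one-sided correlation tests
#'
#' Combines per-study one-sided p-values as
#' `Z = sum(w_i Z_i) / sqrt(sum(w_i^2))` with `Z_i = qnorm(1 - p_i)`, and
#' reports the sample-size-weighted mean correlation
#' `sum(n_i r_i) / sum(n_i)`. Weights default to `sqrt(n)`; unweighted and
#' n-weighted variants are available since conventions differ.
#'
#' @param r per-study correlation coefficients
#' @param n per-study sample sizes
#' @param p per-study one-sided p-values
#' @param weights `"sqrt_n"` (default), `"n"` or `"none"`
#' @return list `combined_z`, `combined_p`, `weighted_r`
#' @export
stouffer_meta <- function(r, n, p, weights = c("sqrt_n", "n", "none")) {
  weights <- match.arg(weights)
  stopifnot(length(r) == length(n), length(n) == length(p), length(p) >= 1L)
  if (any(p <= 0 | p >= 1)) {
    warning("p-values clipped away from {0, 1}")
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  }
  z <- qnorm(1 - p)
  wts <- switch(weights, sqrt_n = sqrt(n), n = n, none = rep(1, length(n)))
  Z <- sum(wts * z) / sqrt(sum(wts^2))
  list(combined_z = Z, combined_p = pnorm(Z, lower.tail = FALSE),
       weighted_r = sum(n * r) / sum(n))
}

#' Cis-mQTL positional enrichment of score SNPs
#'
#' Observed fraction of SNPs lying within `window` bp of any signature CpG,
#' with a permutation p-value from uniform random SNP placement over the
#' genome (probability proportional to chromosome length), floored at
#' `1 / (n_perm + 1)`.
#'
#' @param snp_pos data.frame `chrom`, `pos` of the score SNPs
#' @param cpg_pos data.frame `chrom`, `pos` of the signature CpGs
#' @param genome named vector of chromosome lengths
#' @param window cis window in bp (default 1 Mbp)
#' @param n_perm permutation draws
#' @param seed integer seed
#' @return list `observed_fraction`, `p`, `null_mean`
#' @export
cis_enrichment <- function(snp_pos, cpg_pos, genome, window = 1e6,
                           n_perm = 5000L, seed = 1L) {
  stopifnot(window > 0)
  win <- GenomicRanges::reduce(GenomicRanges::GRanges(
    cpg_pos$chrom,
    IRanges::IRanges(pmax(1, cpg_pos$pos - window), cpg_pos$pos + window)))
  in_cis <- function(chrom, pos) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    IRanges::overlapsAny(gr, win)
  }
  obs <- mean(in_cis(snp_pos$chrom, snp_pos$pos))
  m <- nrow(snp_pos)
  with_seed(split_seed(seed, "cis-perm"), {
    chroms <- sample(names(genome), n_perm * m, replace = TRUE,
                     prob = genome / sum(genome))
    pos <- floor(runif(n_perm * m, 1, genome[chroms] + 1))
    hit <- in_cis(chroms, pos)
    null_frac <- colMeans(matrix(hit, m, n_perm))
  })
  p <- (1 + sum(null_frac >= obs)) / (n_perm + 1)
  list(observed_fraction = obs, p = p, null_mean = mean(null_frac))
}

#' Per-pair mQTL association tests
#'
#' Additive linear regression of each CpG's methylation residual on the
#' paired SNP's minor-allele count, with a Kolmogorov-Smirnov comparison of
#' the resulting p-value distribution against uniform (the null when no
#' genetic control of methylation exists).
#'
#' @param counts sample x SNP minor-allele count matrix
#' @param residuals a [residual_matrix()] (or matrix) of methylation
#'   residuals
#' @param pairs data.frame `snp_id`, `cpg_id`
#' @return list `results` (per-pair beta, r, p; skipped pairs NA with
#'   warning), `ks_stat`, `ks_p`
#' @export
mqtl_tests <- function(counts, residuals, pairs) {
  v <- if (inherits(residuals, "residual_matrix")) residuals$values
       else residuals
  stopifnot(all(c("snp_id", "cpg_id") %in% names(pairs)))
  bad <- !(pairs$snp_id %in% colnames(counts)) |
    !(pairs$cpg_id %in% colnames(v))
  if (any(bad)) stop("pairs reference unknown SNPs or CpGs")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- counts[, pairs$snp_id[i]]
    y <- v[, pairs$cpg_id[i]]
    ok <- !is.na(g) & !is.na(y)
    if (sum(ok) < 3L || sd(g[ok]) == 0)
      return(c(beta = NA_real_, r = NA_real_, p = NA_real_))
    r <- cor(g[ok], y[ok])
    tt <- r * sqrt((sum(ok) - 2) / max(1 - r^2, .Machine$double.xmin))
    c(beta = r * sd(y[ok]) / sd(g[ok]), r = r,
      p = 2 * pt(-abs(tt), df = sum(ok) - 2))
  })
  out <- cbind(pairs, do.call(rbind, res))
  if (anyNA(out$p))
    warning(sum(is.na(out$p)), " monomorphic/degenerate pair(s) skipped")
  pv <- out$p[!is.na(out$p)]
  ks <- suppressWarnings(ks.test(pv, "punif"))
  list(results = out, ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}
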