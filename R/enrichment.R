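
#' Wallenius noncentral hypergeometric probabilities
#'
#' Density and upper-tail probability for the number of "white" items drawn
#' in `n` weighted draws without replacement from `m1` white and `m2`
#' black items, white items having odds `w` relative to black. The density
#' uses the exact integral representation
#' `P(X = x) = C(m1,x) C(m2,n-x) * Int_0^1 (1-t^(w/D))^x (1-t^(1/D))^(n-x) dt`
#' with `D = w(m1-x) + (m2-(n-x))`, evaluated by adaptive quadrature; the
#' support is normalized to absorb quadrature error.
#'
#' @param x count of white items drawn
#' @param m1,m2 white/black totals
#' @param n number of draws
#' @param w odds of a white item
#' @return `dwallenius`: probability mass; `pwallenius_upper`:
#'   `P(X >= x)`
#' @export
dwallenius <- function(x, m1, m2, n, w) {
  lp <- .lwallenius(x, m1, m2, n, w)
  if (is.na(lp)) return(NA_real_)
  exp(lp)
}

# log pmf via the substitution u = t^(1/D):
#   P(X = x) = C(m1,x) C(m2,n-x) * Int_0^1 D u^(D-1) (1-u^w)^x (1-u)^(n-x) du
# evaluated on the log scale (peak-shifted) so large draw counts do not
# underflow the original integrand, which concentrates at exponentially
# small t
.lwallenius <- function(x, m1, m2, n, w) {
  stopifnot(w > 0, n <= m1 + m2)
  lo <- max(0L, n - m2); hi <- min(n, m1)
  if (x < lo || x > hi) return(-Inf)
  if (n == m1 + m2) return(if (x == m1) 0 else -Inf)
  D <- w * (m1 - x) + (m2 - (n - x))
  lg <- function(u)
    log(D) + (D - 1) * log(u) + (n - x) * log1p(-u) + x * log1p(-u^w)
  M <- optimize(lg, c(1e-12, 1 - 1e-12), maximum = TRUE)$objective
  I <- integrate(function(u) exp(lg(u) - M), 0, 1,
                 rel.tol = 1e-10, subdivisions = 1000L)$value
  lchoose(m1, x) + lchoose(m2, n - x) + M + log(I)
}

#' @rdname dwallenius
#' @export
pwallenius_upper <- function(x, m1, m2, n, w) {
  lo <- max(0L, n - m2); hi <- min(n, m1)
  if (x <= lo) return(1)
  if (x > hi) return(0)
  supp <- lo:hi
  lp <- vapply(supp, .lwallenius, numeric(1), m1 = m1, m2 = m2, n = n,
               w = w)
  lp <- lp - max(lp)
  pmf <- exp(lp) / sum(exp(lp))     # normalize away quadrature error
  sum(pmf[supp >= x])
}

# monotone probability-weighting function: binned selection proportions
# made monotone by isotonic regression, evaluated per gene by stepwise
# interpolation on the bias value
.fit_pwf <- function(selected, bias) {
  genes <- names(bias)
  sel <- as.numeric(genes %in% selected)
  ub <- sort(unique(bias))
  n_bins <- min(10L, length(ub))
  breaks <- unique(stats::quantile(bias, probs = seq(0, 1, length.out =
                                                       n_bins + 1L)))
  if (length(breaks) < 2L) return(setNames(rep(1, length(bias)), genes))
  bin <- cut(bias, breaks, include.lowest = TRUE)
  prop <- tapply(sel, bin, mean)
  mid <- tapply(bias, bin, mean)
  ok <- !is.na(prop)
  iso <- isoreg(mid[ok], prop[ok])
  fit <- rep(NA_real_, nlevels(bin))
  fit[which(ok)] <- pmax(iso$yf[order(order(mid[ok]))], 1e-6)  # floor keeps
  w <- fit[as.integer(bin)]                                    # odds finite
  setNames(w, genes)
}

#' Gene-set enrichment with CpG-per-gene bias correction (Wallenius model)
#'
#' Tests each gene set for over-representation among the selected genes
#' (e.g. genes mapped by a CpG signature), correcting for the fact that
#' genes covered by more CpGs are more likely to be selected by chance: a
#' monotone probability-weighting function of the per-gene CpG count is
#' estimated by binned isotonic regression, and each set's p-value comes
#' from the Wallenius noncentral hypergeometric model with odds equal to
#' the mean weight of set genes relative to non-set genes. With uniform
#' bias the model reduces exactly to the central hypergeometric (Fisher)
#' test. Benjamini-Hochberg FDR is attached across the analysed sets.
#'
#' @param selected_genes character vector of selected gene IDs
#' @param gene_bias named numeric vector: per-gene CpG counts over the full
#'   background universe (names define the universe; all counts >= 1)
#' @param sets named list of gene-ID vectors (e.g. from [read_gmt()])
#' @param exclude_genes optional genes removed from universe and sets
#'   (e.g. an extended-MHC mask)
#' @return data.frame `set_id`, `n_genes_in_set`, `n_selected_in_set`,
#'   `odds`, `p`, `fdr`, `method`
#' @export
enrich_wallenius <- function(selected_genes, gene_bias, sets,
                             exclude_genes = NULL) {
  stopifnot(!is.null(names(gene_bias)), all(gene_bias >= 1))
  if (!is.null(exclude_genes))
    gene_bias <- gene_bias[!(names(gene_bias) %in% exclude_genes)]
  universe <- names(gene_bias)
  selected <- intersect(unique(selected_genes), universe)
  if (!length(selected)) stop("no selected gene is in the background universe")
  pwf <- .fit_pwf(selected, gene_bias)
  n_sel <- length(selected)
  rows <- lapply(names(sets), function(id) {
    set <- intersect(sets[[id]], universe)
    if (!length(set)) {
      warning("set '", id, "' has no background gene; skipped")
      return(NULL)
    }
    m1 <- length(set)
    m2 <- length(universe) - m1
    x <- length(intersect(selected, set))
    in_set <- universe %in% set
    odds <- mean(pwf[in_set]) / mean(pwf[!in_set])
    p <- pwallenius_upper(x, m1, m2, n_sel, odds)
    data.frame(set_id = id, n_genes_in_set = m1, n_selected_in_set = x,
               odds = odds, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no analysable gene set")
  out$fdr <- p.adjust(out$p, method = "BH")
  out$method <- "wallenius"
  out[order(out$p), ]
}

#' Percentile-cutoff gene-set enrichment with empirical null
#'
#' Gene scores are `-log10` of the best per-gene association p-value,
#' optionally residualized on per-gene confounders (gene length, SNP count
#' and similar properties that inflate best-SNP statistics). Each set's
#' statistic is the number of member genes scoring above the genome-wide
#' `cutoff_percentile`; its p-value is empirical, from random gene sets of
#' equal size drawn from the scored universe (`n_perm` draws, seeded, with
#' the `1/(n_perm + 1)` floor). Sets outside the size bounds are skipped.
#'
#' @param gene_p named numeric vector of per-gene association p-values
#' @param sets named list of gene-ID vectors
#' @param confounders optional data.frame of per-gene properties (rows
#'   aligned to `names(gene_p)`)
#' @param cutoff_percentile fraction (default 0.75)
#' @param n_perm permutation draws per set
#' @param seed integer seed
#' @param size_range admissible set sizes after restriction to scored genes
#' @return data.frame `set_id`, `n_genes_in_set`, `n_above_cutoff`,
#'   `expected_above`, `p`, `fdr`, `method`
#' @export
enrich_percentile_gsea <- function(gene_p, sets, confounders = NULL,
                                   cutoff_percentile = 0.75,
                                   n_perm = 10000L, seed = 1L,
                                   size_range = c(20L, 200L)) {
  stopifnot(!is.null(names(gene_p)), all(gene_p > 0 & gene_p <= 1))
  score <- -log10(gene_p)
  if (!is.null(confounders)) {
    stopifnot(nrow(confounders) == length(gene_p))
    score <- partial_out(score, confounders)
  }
  names(score) <- names(gene_p)
  thr <- stats::quantile(score, cutoff_percentile)
  above <- score > thr
  N <- length(score)
  rows <- list()
  with_seed(split_seed(seed, "gsea-perm"), {
    for (id in names(sets)) {
      genes <- intersect(sets[[id]], names(score))
      s <- length(genes)
      if (s < size_range[1L] || s > size_range[2L]) next
      obs <- sum(above[genes])
      # a random same-size gene set's count above the cutoff is a draw
      # without replacement from the scored universe
      null_counts <- vapply(seq_len(n_perm), function(b)
        sum(above[sample.int(N, s)]), numeric(1))
      p <- (1 + sum(null_counts >= obs)) / (n_perm + 1)
      rows[[id]] <- data.frame(set_id = id, n_genes_in_set = s,
                               n_above_cutoff = obs,
                               expected_above = s * mean(above), p = p,
                               stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) stop("no gene set within the size bounds")
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$method <- "percentile_gsea"
  rownames(out) <- NULL
  out[order(out$p), ]
}

#' Best-SNP gene scores for percentile GSEA
#'
#' Collapses per-SNP association p-values to genes by taking each gene's
#' minimum p over its mapped SNPs (within the stated flank of the
#' transcript boundaries when positions are supplied).
#'
#' @param snp_p named per-SNP p-values
#' @param gene_map data.frame `snp_id`, `gene`
#' @return named per-gene p-values (best SNP per gene)
#' @export
best_snp_gene_p <- function(snp_p, gene_map) {
  map <- gene_map[gene_map$snp_id %in% names(snp_p), , drop = FALSE]
  tapply(snp_p[map$snp_id], map$gene, min)
}
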