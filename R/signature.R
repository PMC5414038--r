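
#' Select the CpG signature of a component
#'
#' Members are the CpGs whose loadings, in absolute value, exceed `n_sigma`
#' standard deviations from the mean of the component's loading
#' distribution. Heavy-tailed loadings concentrate the signature on a
#' restricted CpG set; the default threshold of 4 sd is deliberately
#' stringent for methylome-scale data (2-3 is typical for expression
#' arrays). Selection is equivariant to affine rescaling of the loadings.
#'
#' @param model an `ica_model`
#' @param component_id component name or index
#' @param n_sigma threshold in sd units (default 4)
#' @return a `cpg_signature`: `cpg_ids`, their `loadings`, `direction`
#'   signs, the threshold and component id
#' @export
select_signature <- function(model, component_id, n_sigma = 4) {
  stopifnot(inherits(model, "ica_model"))
  j <- if (is.character(component_id)) match(component_id, rownames(model$S))
       else as.integer(component_id)
  if (is.na(j) || j < 1L || j > model$k) stop("unknown component")
  s <- model$S[j, ]
  sel <- abs(s - mean(s)) > n_sigma * sd(s)
  structure(list(component_id = rownames(model$S)[j],
                 n_sigma = n_sigma,
                 cpg_ids = names(s)[sel] %||% which(sel),
                 loadings = s[sel],
                 direction = sign(s[sel] - mean(s))),
            class = "cpg_signature")
}

#' @export
print.cpg_signature <- function(x, ...) {
  cat(sprintf("cpg_signature: %d CpGs for %s at n_sigma = %g (%d+, %d-)\n",
              length(x$cpg_ids), x$component_id, x$n_sigma,
              sum(x$direction > 0), sum(x$direction < 0)))
  invisible(x)
}

# GRanges from a transcript annotation table (1-based, closed intervals)
.tx_granges <- function(transcripts) {
  GenomicRanges::GRanges(
    seqnames = transcripts$chrom,
    ranges = IRanges::IRanges(start = transcripts$start,
                              end = transcripts$end),
    strand = transcripts$strand)
}

#' Classify CpGs by genomic context
#'
#' Applies the precedence rules: CpGs within 1,500 bp upstream of the
#' transcription start site of at least one transcript (strand-aware:
#' upstream means 5' of the TSS on the transcript's strand) are `TSS`;
#' CpGs not flagged `TSS` but located within a transcript body (UTRs
#' included) are `Genic`; all remaining CpGs are `Intergenic`. Coordinates
#' are 1-based with closed intervals. CpGs on chromosomes absent from the
#' annotation are `Intergenic` with a warning.
#'
#' @param cpgs data.frame with `cpg_id`, `chrom`, `pos`
#' @param transcripts data.frame with `chrom`, `start`, `end`, `strand`
#' @param tss_upstream upstream window in bp (default 1500)
#' @return data.frame `cpg_id`, `context` (factor TSS/Genic/Intergenic)
#' @export
classify_cpg_context <- function(cpgs, transcripts, tss_upstream = 1500L) {
  stopifnot(all(c("cpg_id", "chrom", "pos") %in% names(cpgs)),
            all(c("chrom", "start", "end", "strand") %in% names(transcripts)))
  if (!all(unique(cpgs$chrom) %in% unique(transcripts$chrom)))
    warning("CpGs on chromosomes absent from the transcript annotation ",
            "are classified Intergenic")
  cpg_gr <- GenomicRanges::GRanges(cpgs$chrom,
                                   IRanges::IRanges(cpgs$pos, cpgs$pos))
  tx_gr <- .tx_granges(transcripts)
  prom <- suppressWarnings(GenomicRanges::trim(GenomicRanges::promoters(
    tx_gr, upstream = tss_upstream, downstream = 0L)))
  in_tss <- suppressWarnings(
    IRanges::overlapsAny(cpg_gr, prom, ignore.strand = TRUE))
  in_tx <- suppressWarnings(
    IRanges::overlapsAny(cpg_gr, tx_gr, ignore.strand = TRUE))
  context <- ifelse(in_tss, "TSS", ifelse(in_tx, "Genic", "Intergenic"))
  data.frame(cpg_id = cpgs$cpg_id,
             context = factor(context,
                              levels = c("TSS", "Genic", "Intergenic")),
             stringsAsFactors = FALSE)
}

#' Map CpGs to genes via transcript annotation
#'
#' A CpG maps to every gene whose transcript body or TSS-upstream window it
#' touches; multi-mapping is allowed (the enrichment machinery corrects for
#' the resulting per-gene CpG multiplicity).
#'
#' @inheritParams classify_cpg_context
#' @return data.frame `cpg_id`, `gene`
#' @export
map_cpgs_to_genes <- function(cpgs, transcripts, tss_upstream = 1500L) {
  cpg_gr <- GenomicRanges::GRanges(cpgs$chrom,
                                   IRanges::IRanges(cpgs$pos, cpgs$pos))
  tx_gr <- .tx_granges(transcripts)
  ext <- suppressWarnings(GenomicRanges::trim(GenomicRanges::punion(
    tx_gr,
    GenomicRanges::promoters(tx_gr, upstream = tss_upstream,
                             downstream = 0L),
    fill.gap = TRUE)))
  hits <- GenomicRanges::findOverlaps(cpg_gr, ext, ignore.strand = TRUE)
  out <- data.frame(
    cpg_id = cpgs$cpg_id[S4Vectors::queryHits(hits)],
    gene = transcripts$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  unique(out)
}

#' One-sample chi-squared test of context distribution vs background
#'
#' Compares the signature's category counts against the background category
#' proportions (goodness of fit, `df = categories - 1`). Cells with
#' expected count below 5 trigger a warning.
#'
#' @param signature_contexts factor/character of the signature CpGs'
#'   categories, or a named count vector
#' @param background_contexts same for the background universe
#' @return list `chi2`, `df`, `p`
#' @export
context_chisq <- function(signature_contexts, background_contexts) {
  as_counts <- function(x) {
    if (is.numeric(x) && !is.null(names(x))) x else table(x)
  }
  obs <- as_counts(signature_contexts)
  bg <- as_counts(background_contexts)
  bg <- bg[names(obs)]
  if (anyNA(bg) || any(bg <= 0))
    stop("all signature categories must have positive background counts")
  expd <- sum(obs) * as.numeric(bg) / sum(bg)
  if (any(expd < 5)) warning("expected count < 5 in at least one cell")
  chi2 <- sum((as.numeric(obs) - expd)^2 / expd)
  df <- length(obs) - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Project a component into an external cohort
#'
#' Computes the component's per-sample pattern in new data as the linear
#' combination of the cohort's scaled residuals with the inverse loadings:
#' the new betas are residualized against the supplied covariates and
#' standardized per CpG, then multiplied by the Moore-Penrose pseudo-inverse
#' of the loadings matrix restricted to the shared CpGs (default), or by the
#' single component's normalized loading row (`method = "single"`). At
#' least 90% of the model's CpGs must be present; missing CpGs are dropped
#' from both sides rather than imputed. The output pattern is standardized
#' to mean 0, unit variance (its sign inherits the model's arbitrary
#' component sign).
#'
#' @param model an `ica_model`
#' @param component_id component name or index
#' @param betas_new a [beta_matrix()] (or residual/plain matrix) for the
#'   target cohort, CpGs in columns
#' @param covariates_new covariate table residualized out of the new betas
#'   (e.g. sex), or `NULL`
#' @param method `"pseudoinverse"` (full k x p inverse loadings) or
#'   `"single"` (one loading row scaled by its squared norm)
#' @param min_overlap minimum fraction of model CpGs required (default 0.9)
#' @return a `component_pattern` for the new cohort
#' @export
project_component <- function(model, component_id, betas_new,
                              covariates_new = NULL,
                              method = c("pseudoinverse", "single"),
                              min_overlap = 0.9) {
  stopifnot(inherits(model, "ica_model"))
  method <- match.arg(method)
  j <- if (is.character(component_id)) match(component_id, rownames(model$S))
       else as.integer(component_id)
  if (is.na(j) || j < 1L || j > model$k) stop("unknown component")
  v <- if (inherits(betas_new, "beta_matrix") ||
           inherits(betas_new, "residual_matrix")) betas_new$values
       else betas_new
  shared <- intersect(colnames(model$S), colnames(v))
  frac <- length(shared) / ncol(model$S)
  if (frac < min_overlap)
    stop(sprintf(
      "only %.1f%% of model CpGs present in the new cohort (%d of %d); >= %.0f%% required",
      100 * frac, length(shared), ncol(model$S), 100 * min_overlap))
  res <- residualize(v[, shared, drop = FALSE], covariates_new)
  shared <- colnames(res$values)            # degenerate CpGs may have dropped
  R <- res$values
  S <- model$S[, shared, drop = FALSE]
  w <- if (method == "pseudoinverse") {
    (R %*% t(S) %*% solve(tcrossprod(S)))[, j]
  } else {
    drop(R %*% S[j, ]) / sum(S[j, ]^2)
  }
  w <- scale(w)[, 1L]
  structure(list(weights = setNames(w, rownames(R)),
                 component_id = rownames(model$S)[j],
                 stability = NA_real_, dominance = NA_real_,
                 n_cpgs_used = length(shared), method = method),
            class = "component_pattern")
}

#' Overlap odds ratio and hypergeometric enrichment p
#'
#' 2x2 overlap test between two CpG (or gene) sets within a stated
#' universe: odds ratio of the contingency table and the one-sided
#' hypergeometric tail probability of at least the observed overlap.
#' Degenerate tables (a zero off-diagonal cell) report `Inf` alongside a
#' Haldane-corrected finite estimate.
#'
#' @param set_a,set_b character vectors (or other atomic IDs)
#' @param universe size of the universe both sets live in
#' @return list `odds_ratio`, `odds_ratio_haldane`, `overlap`, `p`
#' @export
overlap_or <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) || !length(set_b)) stop("empty set")
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  cc <- length(set_b) - a
  d <- universe - a - b - cc
  if (d < 0) stop("universe smaller than the union of the sets")
  or <- (a * d) / (b * cc)
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  p <- phyper(a - 1L, length(set_a), universe - length(set_a),
              length(set_b), lower.tail = FALSE)
  list(odds_ratio = or, odds_ratio_haldane = or_h, overlap = a, p = p)
}
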