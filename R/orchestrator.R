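
#' Pipeline configuration
#'
#' Collects every tunable the end-to-end driver uses. Exactly one of
#' `input_dir` (a directory of TSV fixtures as written by [write_cohort()])
#' or `design` (a [cohort_design()], simulated on the fly) must be given.
#'
#' @param input_dir directory with betas.tsv, phenotypes.tsv, cpgs.tsv,
#'   transcripts.tsv and optionally genotypes.tsv/snp_map.tsv
#' @param design a [cohort_design()] to simulate instead of reading files
#' @param out_dir output directory for stage results and the manifest
#' @param seed master seed; every stochastic stage splits from it
#' @param max_missing,k_neighbours,n_sv preprocessing parameters
#' @param k,n_restarts,dominance decomposition parameters
#' @param n_sigma signature threshold in sd units
#' @param n_boot mediation bootstrap resamples
#' @param age_var_x,age_var_y which age variable is partialled out of the
#'   methylomic pattern (x side) and of phenotypes (y side); recorded in
#'   the manifest
#' @param do_genetics,do_enrichment stage toggles
#' @param gmt optional path to a GMT gene-set collection for enrichment
#' @param stouffer_weights Stouffer weighting variant (recorded)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(input_dir = NULL, design = NULL, out_dir,
                            seed = 1L, max_missing = 0.05,
                            k_neighbours = 10L, n_sv = 0L, k = "auto",
                            n_restarts = 30L, dominance = 0.10,
                            n_sigma = 4, n_boot = 2000L,
                            age_var_x = "age_blood", age_var_y = "age_main",
                            do_genetics = TRUE, do_enrichment = FALSE,
                            gmt = NULL, stouffer_weights = "sqrt_n") {
  if (is.null(input_dir) == is.null(design))
    stop("give exactly one of input_dir or design")
  structure(as.list(environment()), class = "pipeline_config")
}

.read_cohort_dir <- function(dir) {
  need <- c("betas.tsv", "phenotypes.tsv", "cpgs.tsv", "transcripts.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) stop("input_dir lacks: ", paste(miss, collapse = ", "))
  out <- list(
    betas = read_beta_tsv(file.path(dir, "betas.tsv")),
    phenotypes = data.table::fread(file.path(dir, "phenotypes.tsv"),
                                   data.table = FALSE),
    annotation = list(
      cpgs = data.table::fread(file.path(dir, "cpgs.tsv"),
                               data.table = FALSE),
      transcripts = data.table::fread(file.path(dir, "transcripts.tsv"),
                                      data.table = FALSE)))
  chroms <- unique(out$annotation$cpgs$chrom)
  out$annotation$genome <- setNames(
    vapply(chroms, function(ch) {
      max(out$annotation$cpgs$pos[out$annotation$cpgs$chrom == ch],
          out$annotation$transcripts$end[
            out$annotation$transcripts$chrom == ch], 0) + 1e6
    }, numeric(1)), chroms)
  if (file.exists(file.path(dir, "genotypes.tsv")))
    out$genotypes <- list(
      counts = read_matrix_tsv(file.path(dir, "genotypes.tsv")),
      map = data.table::fread(file.path(dir, "snp_map.tsv"),
                              data.table = FALSE))
  out
}

#' Run the full pipeline
#'
#' Executes preprocess, decompose, associate, mediate, signature,
#' regional EFA and (optionally) genetic-score and enrichment stages in
#' order, failing fast with stage-attributed errors, writing stage outputs
#' as TSV under `out_dir` and returning (and writing) a run manifest
#' sufficient to re-run bit-identically.
#'
#' The "pattern of interest" carried into mediation, signature and scoring
#' is the retained component with the strongest absolute age correlation
#' whose age-adjusted thickness association is strongest — mirroring the
#' decision rule of the motivating analysis.
#'
#' @param config a [pipeline_config()]
#' @return list with all stage results and the `manifest`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    ml_log("pipeline", "stage %s ...", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("input", {
    if (!is.null(config$design)) simulate_cohort(config$design,
                                                 genotypes = config$do_genetics)
    else .read_cohort_dir(config$input_dir)
  })
  phen <- cohort$phenotypes
  pre <- stage("preprocess", preprocess_betas(
    cohort$betas, protected = phen$age_blood,
    known = data.frame(sex = phen$sex),
    max_missing_rate = config$max_missing,
    k_neighbours = config$k_neighbours, n_sv = config$n_sv))
  model <- stage("decompose", decompose_methylome(
    pre$residuals, k = config$k, n_restarts = config$n_restarts,
    dominance = config$dominance, seed = split_seed(config$seed, "decompose")))
  assoc <- stage("associate", {
    fam <- sum(model$retained)
    targets <- phen[, c("age_blood", "age_main", "thickness_global",
                        "memory"), drop = FALSE]
    associate_components(model, targets)
  })
  # pattern of interest: strongest age association among retained components
  age_rows <- assoc[assoc$phenotype == "age_blood", ]
  poi <- age_rows$component[which.max(abs(age_rows$r))]
  adj_x <- data.frame(age = phen[[config$age_var_x]])
  adj_y <- data.frame(age = phen[[config$age_var_y]])
  poi_thick <- adjusted_cor(model$A[, poi], phen$thickness_global,
                            z_x = adj_x, z_y = adj_y)
  med <- stage("mediate", mediate(
    phen[[config$age_var_y]], model$A[, poi], phen$thickness_global,
    n_boot = config$n_boot, seed = split_seed(config$seed, "mediate")))
  sig <- stage("signature", select_signature(model, poi, config$n_sigma))
  ctx <- stage("context", {
    contexts <- classify_cpg_context(cohort$annotation$cpgs,
                                     cohort$annotation$transcripts)
    in_sig <- contexts$cpg_id %in% sig$cpg_ids
    if (any(in_sig) && sum(in_sig) >= 3L)
      list(contexts = contexts,
           chisq = context_chisq(contexts$context[in_sig],
                                 contexts$context))
    else list(contexts = contexts, chisq = NULL)
  })
  efa <- stage("regional_efa", {
    regions <- data.matrix(phen[, grep("^region_", names(phen)),
                                drop = FALSE])
    adj <- residualize(regions, data.frame(sex = phen$sex,
                                           age = phen$age_main))
    nf <- pa_nfactors(adj$values, n_iter = 200L,
                      seed = split_seed(config$seed, "pa"))
    nf <- max(nf, 1L)
    fm <- fit_efa(adj$values, nf)
    scores <- efa_scores(fm, adj$values)
    poi_adj <- partial_out(model$A[, poi], adj_x)
    fa <- lapply(seq_len(nf), function(j)
      assoc_cor(scores[, j], poi_adj, n_tests = nf))
    list(model = fm, scores = scores, associations = fa, n_factors = nf)
  })
  gen <- NULL
  if (config$do_genetics && !is.null(cohort$genotypes)) {
    gen <- stage("genescore", {
      qc <- snp_qc(cohort$genotypes$counts)
      poi_adj <- partial_out(model$A[, poi],
                             data.frame(age = phen$age_blood))
      gs <- build_gene_score(qc$counts, poi_adj, cohort$genotypes$map)
      em <- score_cor_test(gs, phen$memory, sidedness = "less")
      sig_pos <- cohort$annotation$cpgs[
        cohort$annotation$cpgs$cpg_id %in% sig$cpg_ids, ]
      snp_pos <- cohort$genotypes$map[
        cohort$genotypes$map$snp_id %in% gs$snps, ]
      cis <- cis_enrichment(snp_pos, sig_pos, cohort$annotation$genome,
                            n_perm = 2000L,
                            seed = split_seed(config$seed, "cis"))
      pairs <- expand.grid(snp_id = gs$snps,
                           cpg_id = intersect(sig$cpg_ids,
                                              colnames(pre$residuals$values)),
                           stringsAsFactors = FALSE)
      mq <- if (nrow(pairs)) mqtl_tests(qc$counts, pre$residuals, pairs)
            else NULL
      list(qc = qc$stats, score = gs, memory_test = em, cis = cis,
           mqtl = mq)
    })
  }
  enr <- NULL
  if (config$do_enrichment && !is.null(config$gmt)) {
    enr <- stage("enrichment", {
      sets <- read_gmt(config$gmt)
      c2g <- map_cpgs_to_genes(cohort$annotation$cpgs,
                               cohort$annotation$transcripts)
      bias <- table(c2g$gene)
      sig_genes <- unique(c2g$gene[c2g$cpg_id %in% sig$cpg_ids])
      enrich_wallenius(sig_genes, setNames(as.numeric(bias), names(bias)),
                       sets)
    })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("methylica")),
    seed = config$seed,
    parameters = list(
      max_missing = config$max_missing, k_neighbours = config$k_neighbours,
      n_sv = pre$manifest$n_sv, k = model$k,
      n_restarts = config$n_restarts, dominance = config$dominance,
      n_sigma = config$n_sigma, n_boot = config$n_boot,
      age_var_x = config$age_var_x, age_var_y = config$age_var_y,
      bonferroni_components = sum(model$retained),
      bonferroni_factors = efa$n_factors,
      stouffer_weights = config$stouffer_weights),
    pattern_of_interest = poi,
    stage_seeds = list(
      decompose = split_seed(config$seed, "decompose"),
      mediate = split_seed(config$seed, "mediate"),
      pa = split_seed(config$seed, "pa"),
      cis = split_seed(config$seed, "cis")))
  # stage outputs
  write_matrix_tsv(model$A, file.path(config$out_dir, "weights.tsv"))
  write_matrix_tsv(model$S, file.path(config$out_dir, "loadings.tsv"),
                   id_col = "component")
  data.table::fwrite(data.frame(component = colnames(model$A),
                                stability = model$stability,
                                dominance = model$dominance,
                                retained = model$retained),
                     file.path(config$out_dir, "diagnostics.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(assoc, file.path(config$out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(preprocess = pre, model = model, associations = assoc,
       pattern_of_interest = poi, poi_thickness = poi_thick,
       mediation = med, signature = sig, context = ctx, efa = efa,
       genetics = gen, enrichment = enr, manifest = manifest)
}
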