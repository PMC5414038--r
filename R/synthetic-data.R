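
#' Design for a synthetic methylome cohort
#'
#' Describes the statistical world the generator emulates: `n_components`
#' sparse latent methylomic signatures with heavy-tailed CpG loadings, one of
#' which carries an age signal and partially mediates an age-to-cortical
#' thickness effect; a factor structure over 68 regional thickness measures;
#' cis-mQTL genetic effects on the CpGs of the age-loaded component; and
#' nuisance structure (sex, batch, cell composition) for surrogate-variable
#' machinery to absorb.
#'
#' Defaults state the world at desk scale: a cohort of 300 young adults
#' (ages 18-35), 20,000 CpGs, 5 components with active-loading magnitude
#' around 4 sd. The correlation targets default to the mediation triple
#' r(age, component) = 0.29, r(component, thickness) = -0.24 marginal, with
#' the direct age effect chosen so the total age-thickness correlation is
#' -0.27. Regional factors default to 8 factors with loadings 0.7, so the
#' factor structure explains about 49% of regional variance.
#'
#' @param n_samples,n_cpgs,n_components cohort dimensions and true order k
#' @param sparsity fraction of CpGs with non-null loading per component
#' @param loading_scale mean absolute magnitude (in sd units) of active
#'   loadings; active loadings are drawn as `sign * |N(loading_scale, 1)|`
#' @param age_component_index which component carries the age signal
#' @param r_age_component target correlation of that component's sample
#'   weights with age
#' @param r_component_thickness target marginal correlation of the component
#'   with global cortical thickness
#' @param r_age_thickness_direct direct (partial) age effect on thickness;
#'   the implied total age-thickness correlation is
#'   `r_age_thickness_direct + b * r_age_component` with
#'   `b = r_component_thickness - r_age_thickness_direct * r_age_component`
#' @param r_factor_component target correlation of the mediating regional
#'   thickness factor with the component
#' @param r_memory_component target correlation of episodic memory with the
#'   component (negative: higher pattern weight, poorer recall)
#' @param n_factors_regions,n_regions regional thickness factor structure
#' @param region_loading,region_noise loading of each region on its factor
#'   and residual noise sd (default `sqrt(1 - region_loading^2)`)
#' @param n_snps,cis_fraction,mqtl_effect genotype design: SNP count,
#'   fraction placed in cis (within `cis_window` bp) of the age component's
#'   active CpGs, and per-minor-allele shift of the component weight (sd
#'   units); cis SNPs are the causal ones
#' @param cis_window cis window in bp (default 1 Mbp)
#' @param geno_missing_rate fraction of genotype calls set missing
#' @param signal_amplitude multiplier applied to the combined latent signal
#'   `A S` (and nuisance signals) on the logit scale before squashing; the
#'   default 0.2 keeps per-CpG methylation shifts in the realistic
#'   few-percent range and the logistic map effectively monotone-linear
#' @param noise_sd residual noise sd on the logit (M-value-like) scale
#' @param sex_effect,batch_effect,cell_effect amplitudes of the nuisance
#'   signals planted in the methylome (0 disables)
#' @param seed master integer seed; all stages split from it
#' @return a validated list of class `cohort_design`
#' @export
cohort_design <- function(n_samples = 300, n_cpgs = 20000, n_components = 5,
                          sparsity = 0.01, loading_scale = 4,
                          age_component_index = 2,
                          r_age_component = 0.29,
                          r_component_thickness = -0.24,
                          r_age_thickness_direct = -0.2188,
                          r_factor_component = -0.13,
                          r_memory_component = -0.138,
                          n_factors_regions = 8, n_regions = 68,
                          region_loading = 0.7,
                          region_noise = sqrt(1 - region_loading^2),
                          n_snps = 60, cis_fraction = 0.53,
                          mqtl_effect = 0.5, cis_window = 1e6,
                          geno_missing_rate = 0.01,
                          signal_amplitude = 0.2,
                          noise_sd = 1,
                          sex_effect = 1, batch_effect = 1, cell_effect = 1,
                          seed = 1L) {
  d <- as.list(environment())
  counts <- c("n_samples", "n_cpgs", "n_components", "n_factors_regions",
              "n_regions", "n_snps")
  for (nm in counts)
    if (d[[nm]] < 1 || d[[nm]] != round(d[[nm]]))
      stop("design field '", nm, "' must be a positive integer")
  for (nm in c("sparsity", "cis_fraction"))
    if (d[[nm]] <= 0 || d[[nm]] >= 1)
      stop("design field '", nm, "' must be a fraction in (0, 1)")
  for (nm in c("r_age_component", "r_component_thickness",
               "r_age_thickness_direct", "r_factor_component",
               "r_memory_component"))
    if (abs(d[[nm]]) >= 1) stop("correlation target '", nm, "' not in (-1, 1)")
  if (d$age_component_index > d$n_components)
    stop("age_component_index exceeds n_components")
  if (d$n_factors_regions > d$n_regions)
    stop("more regional factors than regions")
  # implied (age, component, thickness) correlation matrix must be PSD and
  # the structural noise variance non-negative
  tri <- implied_triple(d)
  R <- matrix(c(1, tri["r_xm"], tri["r_xy"],
                tri["r_xm"], 1, tri["r_my"],
                tri["r_xy"], tri["r_my"], 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-12 ||
      tri["noise_var"] < 0)
    stop("design correlation targets violate positive semi-definiteness of ",
         "the implied (age, component, thickness) correlation matrix")
  structure(d, class = "cohort_design")
}

# Solve the structural thickness equation y = c'x + b m + e for the implied
# marginal correlations and noise variance.
implied_triple <- function(design) {
  r_xm <- design$r_age_component
  cp <- design$r_age_thickness_direct
  b <- design$r_component_thickness - cp * r_xm
  r_xy <- cp + b * r_xm
  r_my <- b + cp * r_xm
  c(r_xm = r_xm, r_my = r_my, r_xy = r_xy, b = b, c_prime = cp,
    noise_var = 1 - (cp^2 + b^2 + 2 * cp * b * r_xm))
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "cohort_design: n=%d, p=%d, k=%d (age component %d), seed=%d\n",
    x$n_samples, x$n_cpgs, x$n_components, x$age_component_index, x$seed))
  tri <- implied_triple(x)
  cat(sprintf("  targets: r(age,comp)=%.3f r(comp,thick)=%.3f r(age,thick)=%.3f\n",
              tri["r_xm"], tri["r_my"], tri["r_xy"]))
  invisible(x)
}

#' Generate the synthetic methylome
#'
#' Draws sample weights `A` (n x k, standard normal columns) and sparse
#' heavy-tailed loadings `S` (k x p; each component activates
#' `round(sparsity * n_cpgs)` CpGs with loadings `sign * |N(loading_scale, 1)|`),
#' adds planted sex/batch/cell-composition nuisance signals and iid noise on
#' a logit scale around per-CpG baselines drawn from a
#' hypo/hemi/hyper-methylated mixture, and squashes through the logistic map
#' to beta values in (0, 1).
#'
#' @param design a [cohort_design()]
#' @return list with `betas` (a [beta_matrix()]) and `truth` (class
#'   `cohort_truth`: true `A`, `S`, active CpG sets, nuisance factors,
#'   baselines and the design)
#' @export
generate_methylome <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_samples; p <- design$n_cpgs; k <- design$n_components
  with_seed(split_seed(design$seed, "methylome"), {
    A <- matrix(rnorm(n * k), n, k)
    A <- standardize_cols(A)
    m_active <- max(1L, round(design$sparsity * p))
    S <- matrix(0, k, p)
    active <- vector("list", k)
    for (j in seq_len(k)) {
      idx <- sort(sample.int(p, m_active))
      active[[j]] <- idx
      S[j, idx] <- sample(c(-1, 1), m_active, replace = TRUE) *
        abs(rnorm(m_active, design$loading_scale, 1))
    }
    # nuisance: sex (binary), batch (3 levels), cell-composition factor
    sex <- sample(0:1, n, replace = TRUE)
    batch <- sample(1:3, n, replace = TRUE)
    cellf <- rnorm(n)
    nuis <- cbind(sex = sex - mean(sex),
                  batch = scale(as.numeric(batch))[, 1L],
                  cell = cellf)
    S_nuis <- matrix(0, 3L, p)
    amps <- c(design$sex_effect, design$batch_effect, design$cell_effect)
    for (j in 1:3) if (amps[j] > 0) {
      idx <- sample.int(p, max(1L, round(0.05 * p)))
      S_nuis[j, idx] <- amps[j] * rnorm(length(idx))
    }
    mu_class <- sample(1:3, p, replace = TRUE, prob = c(0.35, 0.30, 0.35))
    mu <- rnorm(p, mean = c(-3, 0, 3)[mu_class], sd = 0.5)
    signal <- A %*% S
    logit <- sweep(design$signal_amplitude * (signal + nuis %*% S_nuis),
                   2L, mu, `+`)
    if (design$noise_sd > 0)
      logit <- logit + matrix(rnorm(n * p, sd = design$noise_sd), n, p)
    betas <- beta_matrix(plogis(logit))
    truth <- structure(
      list(A = A, S = S, active = active,
           age_component = design$age_component_index,
           signal = signal, mu = mu,
           sex = sex, batch = batch, cell_factor = cellf,
           design = design),
      class = "cohort_truth")
    list(betas = betas, truth = truth)
  })
}

#' Replicate a methylome cohort from existing truth
#'
#' Draws a new, independent sample of individuals from the same latent
#' world: same loadings `S`, active CpG sets and per-CpG baselines, new
#' mixing weights, nuisance factors and noise. The replication analogue of
#' projecting a trained component into an external cohort.
#'
#' @param truth a `cohort_truth` from [generate_methylome()]
#' @param n_samples size of the replication cohort
#' @param seed integer seed (independent of the training seed)
#' @return list with `betas` and `truth` for the new cohort
#' @export
replicate_methylome <- function(truth, n_samples, seed) {
  stopifnot(inherits(truth, "cohort_truth"))
  design <- truth$design
  p <- design$n_cpgs; k <- design$n_components
  with_seed(split_seed(seed, "replicate"), {
    A <- standardize_cols(matrix(rnorm(n_samples * k), n_samples, k))
    sex <- sample(0:1, n_samples, replace = TRUE)
    nuis <- cbind(sex - mean(sex), scale(rnorm(n_samples))[, 1L],
                  rnorm(n_samples))
    S_nuis <- matrix(0, 3L, p)  # fresh nuisance loadings, same amplitudes
    amps <- c(design$sex_effect, design$batch_effect, design$cell_effect)
    for (j in 1:3) if (amps[j] > 0) {
      idx <- sample.int(p, max(1L, round(0.05 * p)))
      S_nuis[j, idx] <- amps[j] * rnorm(length(idx))
    }
    signal <- A %*% truth$S
    logit <- sweep(design$signal_amplitude * (signal + nuis %*% S_nuis),
                   2L, truth$mu, `+`)
    if (design$noise_sd > 0)
      logit <- logit +
        matrix(rnorm(n_samples * p, sd = design$noise_sd), n_samples, p)
    b <- plogis(logit)
    dimnames(b) <- list(sprintf("R%04d", seq_len(n_samples)),
                        sprintf("cg%07d", seq_len(p)))
    new_truth <- truth
    new_truth$A <- A
    new_truth$sex <- sex
    new_truth$signal <- signal
    list(betas = beta_matrix(b), truth = new_truth)
  })
}

#' Generate phenotypes for a synthetic cohort
#'
#' Age is uniform on 18-35 years (age at the main investigation) with blood
#' sampling up to ~3.8 years later, correlated with the age-loaded
#' component's true weights at the design target. Global cortical thickness
#' follows the structural equation
#' `thickness = c' * age + b * component + noise` on the standardized scale
#' (reported in mm around 2.5), regional thickness measures arise from
#' `n_factors_regions` orthogonal factors (one of them loaded on the
#' mediating component), and the episodic-memory score loads negatively on
#' the component. Cell counts track the planted cell-composition factor;
#' smoking is mildly loaded on the component.
#'
#' @param design a [cohort_design()]
#' @param truth the `cohort_truth` from [generate_methylome()]
#' @return list with `phenotypes` (data.frame, one row per sample) and
#'   `truth` (true factor scores/loadings, standardized age, structural
#'   coefficients) for sharp downstream testing
#' @export
generate_phenotypes <- function(design, truth) {
  stopifnot(inherits(design, "cohort_design"), inherits(truth, "cohort_truth"))
  n <- design$n_samples
  w <- scale(truth$A[, truth$age_component])[, 1L]
  tri <- implied_triple(design)
  with_seed(split_seed(design$seed, "phenotypes"), {
    # latent normal correlated with w, pushed through Phi to a uniform age;
    # correlations below use the realized standardized age, so targets hold
    r <- design$r_age_component
    rho <- max(-0.999, min(0.999, r / 0.97720502))  # Phi-transform attenuation
    z_age <- rho * w + sqrt(1 - rho^2) * rnorm(n)
    age_main <- 18 + 17 * pnorm(z_age)
    age_blood <- age_main + runif(n, 1 / 365, 3.8)
    age_z <- scale(age_main)[, 1L]
    thick_z <- tri["c_prime"] * age_z + tri["b"] * w +
      sqrt(max(0, tri["noise_var"])) * rnorm(n)
    thickness_global <- 2.5 + 0.12 * thick_z

    q <- design$n_factors_regions
    Fmat <- matrix(rnorm(n * q), n, q)
    med_factor <- min(6L, q)  # the factor tied to the mediating component
    rf <- design$r_factor_component
    Fmat[, med_factor] <- rf * w + sqrt(1 - rf^2) * rnorm(n)
    fac_of_region <- rep(seq_len(q), length.out = design$n_regions)
    lambda <- design$region_loading
    regions <- Fmat[, fac_of_region, drop = FALSE] * lambda +
      design$region_noise * matrix(rnorm(n * design$n_regions), n)
    regions <- 2.5 + 0.15 * regions
    colnames(regions) <- sprintf("region_%02d", seq_len(design$n_regions))

    rm_ <- design$r_memory_component
    memory <- rm_ * w + sqrt(1 - rm_^2) * rnorm(n)

    lymph <- 30 + 6 * (0.7 * truth$cell_factor + 0.3 * rnorm(n))
    neut <- 55 + 8 * (-0.6 * truth$cell_factor + 0.4 * rnorm(n))
    mixed <- 12 + 3 * rnorm(n)
    smoke_latent <- 0.17 * w + sqrt(1 - 0.17^2) * rnorm(n)
    smoking <- findInterval(pnorm(smoke_latent), c(0.55, 0.75, 0.90, 0.97))
    alcohol <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.6, 0.1))
    cannabis <- sample(0:2, n, replace = TRUE, prob = c(0.7, 0.25, 0.05))
    bmi <- 22 + 3 * rnorm(n)

    phen <- data.frame(
      sample_id = rownames(truth$A) %||% sprintf("S%04d", seq_len(n)),
      age_main = age_main, age_blood = age_blood, sex = truth$sex,
      thickness_global = thickness_global, regions, memory = memory,
      lymphocytes = lymph, neutrophils = neut, mixed_cells = mixed,
      smoking = smoking, alcohol = alcohol, cannabis = cannabis, bmi = bmi,
      stringsAsFactors = FALSE, check.names = FALSE)
    rownames(phen) <- NULL
    list(phenotypes = phen,
         truth = list(factor_scores = Fmat,
                      factor_of_region = fac_of_region,
                      mediating_factor = med_factor,
                      age_z = age_z, component_w = w,
                      coefficients = tri))
  })
}

#' Generate CpG and transcript annotation for a synthetic genome
#'
#' A desk-scale genome of four 60-Mbp chromosomes. CpGs get uniform unique
#' positions and island-context labels with array-like proportions;
#' transcripts are random stranded intervals (1-based, closed).
#'
#' @param design a [cohort_design()]
#' @param n_transcripts number of transcripts to place
#' @return list with `cpgs` (cpg_id, chrom, pos, island_context),
#'   `transcripts` (gene_id, transcript_id, chrom, start, end, strand) and
#'   `genome` (named vector of chromosome lengths)
#' @export
generate_annotation <- function(design, n_transcripts = 800) {
  stopifnot(inherits(design, "cohort_design"))
  p <- design$n_cpgs
  genome <- setNames(rep(6e7, 4), paste0("chr", 1:4))
  with_seed(split_seed(design$seed, "annotation"), {
    chrom <- sample(names(genome), p, replace = TRUE)
    pos <- integer(p)
    for (ch in names(genome))
      pos[chrom == ch] <- sample.int(genome[[ch]], sum(chrom == ch))
    ctx <- sample(c("Island", "Shore", "Shelf", "OpenSea"), p, replace = TRUE,
                  prob = c(0.15, 0.25, 0.10, 0.50))
    cpgs <- data.frame(cpg_id = sprintf("cg%07d", seq_len(p)),
                       chrom = chrom, pos = pos, island_context = ctx,
                       stringsAsFactors = FALSE)
    tchrom <- sample(names(genome), n_transcripts, replace = TRUE)
    tlen <- round(runif(n_transcripts, 5e3, 2e5))
    tstart <- vapply(seq_len(n_transcripts), function(i)
      sample.int(genome[[tchrom[i]]] - tlen[i], 1L), numeric(1))
    tx <- data.frame(
      gene_id = sprintf("GENE%04d", seq_len(n_transcripts)),
      transcript_id = sprintf("TX%05d", seq_len(n_transcripts)),
      chrom = tchrom, start = tstart, end = tstart + tlen - 1,
      strand = sample(c("+", "-"), n_transcripts, replace = TRUE),
      stringsAsFactors = FALSE)
    list(cpgs = cpgs, transcripts = tx, genome = genome)
  })
}

#' Generate genotypes with planted cis-mQTL effects
#'
#' SNPs get minor-allele frequencies uniform on (0.05, 0.5) and
#' Hardy-Weinberg genotype draws. A design-stated fraction of SNPs is placed
#' in cis (within `cis_window`) of the age-loaded component's active CpGs;
#' those cis SNPs are causal: each minor allele shifts the component weight
#' by `mqtl_effect` sd units, realised by tilting the per-allele Bernoulli
#' probability with the sample's true component weight (so
#' `mqtl_effect = 0` reduces to plain Hardy-Weinberg draws).
#'
#' @param design a [cohort_design()]
#' @param truth the `cohort_truth` from [generate_methylome()]
#' @param annotation output of [generate_annotation()]
#' @param maf optional per-SNP minor allele frequencies (recycled); must lie
#'   in (0, 0.5]
#' @return list with `counts` (sample x SNP minor-allele counts, NA for
#'   missing calls) and `map` (snp_id, chrom, pos, gene, maf, causal)
#' @export
generate_genotypes <- function(design, truth, annotation, maf = NULL) {
  stopifnot(inherits(design, "cohort_design"), inherits(truth, "cohort_truth"))
  n <- design$n_samples; m <- design$n_snps
  genome <- annotation$genome
  with_seed(split_seed(design$seed, "genotypes"), {
    if (is.null(maf)) maf <- runif(m, 0.05, 0.5)
    maf <- rep_len(maf, m)
    if (any(maf <= 0 | maf > 0.5))
      stop("minor allele frequencies must lie in (0, 0.5]")
    n_cis <- round(design$cis_fraction * m)
    act <- annotation$cpgs[truth$active[[truth$age_component]], ]
    chrom <- character(m); pos <- numeric(m)
    # constructive cis placement near random active CpGs
    anchor <- act[sample.int(nrow(act), n_cis, replace = TRUE), ]
    chrom[seq_len(n_cis)] <- anchor$chrom
    pos[seq_len(n_cis)] <- pmin(
      pmax(1, anchor$pos + round(runif(n_cis, -design$cis_window,
                                       design$cis_window))),
      genome[anchor$chrom])
    # trans placement by rejection outside every cis window
    i <- n_cis + 1L
    while (i <= m) {
      ch <- sample(names(genome), 1L)
      pp <- sample.int(genome[[ch]], 1L)
      near <- act$chrom == ch & abs(act$pos - pp) <= design$cis_window
      if (!any(near)) { chrom[i] <- ch; pos[i] <- pp; i <- i + 1L }
    }
    causal <- seq_len(m) <= n_cis
    w <- scale(truth$A[, truth$age_component])[, 1L]
    counts <- matrix(NA_integer_, n, m)
    for (j in seq_len(m)) {
      p_allele <- if (causal[j] && design$mqtl_effect != 0)
        plogis(qlogis(maf[j]) + design$mqtl_effect * w)
      else rep(maf[j], n)
      counts[, j] <- rbinom(n, 1L, p_allele) + rbinom(n, 1L, p_allele)
    }
    if (design$geno_missing_rate > 0) {
      miss <- matrix(runif(n * m) < design$geno_missing_rate, n, m)
      counts[miss] <- NA_integer_
    }
    dimnames(counts) <- list(rownames(truth$A) %||%
                               sprintf("S%04d", seq_len(n)),
                             sprintf("rs%06d", seq_len(m)))
    map <- data.frame(snp_id = colnames(counts), chrom = chrom, pos = pos,
                      gene = sprintf("GENE%04d", seq_len(m)),
                      maf = maf, causal = causal, stringsAsFactors = FALSE)
    list(counts = counts, map = map)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_methylome()],
#' [generate_phenotypes()], [generate_annotation()] and
#' [generate_genotypes()] under one design.
#'
#' @param design a [cohort_design()]
#' @param genotypes generate the genotype block? (slowest part at large n)
#' @return list with `betas`, `truth`, `phenotypes`, `phenotype_truth`,
#'   `annotation` and (optionally) `genotypes`
#' @export
simulate_cohort <- function(design, genotypes = TRUE) {
  meth <- generate_methylome(design)
  phen <- generate_phenotypes(design, meth$truth)
  ann <- generate_annotation(design)
  out <- list(betas = meth$betas, truth = meth$truth,
              phenotypes = phen$phenotypes, phenotype_truth = phen$truth,
              annotation = ann)
  if (genotypes)
    out$genotypes <- generate_genotypes(design, meth$truth, ann)
  out
}

#' Write a simulated cohort to plain-text files
#'
#' Serializes the fixtures the pipeline reads: beta matrix TSV, phenotype
#' TSV, CpG annotation TSV (1-based positions), transcript TSV (1-based
#' closed intervals), genotype TSV and a JSON truth summary (which component
#' is age-loaded, active CpG sets, seeds).
#'
#' @param cohort output of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$betas$values, file.path(dir, "betas.tsv"))
  data.table::fwrite(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(cohort$annotation$cpgs, file.path(dir, "cpgs.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(cohort$annotation$transcripts,
                     file.path(dir, "transcripts.tsv"), sep = "\t",
                     quote = FALSE)
  if (!is.null(cohort$genotypes)) {
    write_matrix_tsv(cohort$genotypes$counts, file.path(dir, "genotypes.tsv"))
    data.table::fwrite(cohort$genotypes$map, file.path(dir, "snp_map.tsv"),
                       sep = "\t", quote = FALSE)
  }
  truth <- cohort$truth
  jsonlite::write_json(
    list(age_component = truth$age_component,
         active = lapply(truth$active, identity),
         seed = truth$design$seed,
         design = unclass(truth$design)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
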