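# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a clean planted world (no nuisance) for decomposition-centred tests
clean_design <- function(n = 200, p = 5000, k = 3, seed = 5, ...) {
  cohort_design(n_samples = n, n_cpgs = p, n_components = k, seed = seed,
                sex_effect = 0, batch_effect = 0, cell_effect = 0, ...)
}

# cohort + decomposition reused across signature/projection tests
decomposed_fixture <- function() {
  fixture("decomposed", function() {
    d <- clean_design(loading_scale = 5)
    co <- generate_methylome(d)
    res <- residualize(co$betas)
    model <- decompose_methylome(res, k = 3, n_restarts = 5, seed = 2)
    list(design = d, cohort = co, residuals = res, model = model)
  })
}

# genotype world with planted cis-mQTLs
genetic_fixture <- function() {
  fixture("genetic", function() {
    d <- cohort_design(n_samples = 500, n_cpgs = 3000, n_components = 3,
                       seed = 6, n_snps = 57, cis_fraction = 0.53,
                       mqtl_effect = 0.5)
    co <- generate_methylome(d)
    ann <- generate_annotation(d)
    geno <- generate_genotypes(d, co$truth, ann)
    list(design = d, cohort = co, annotation = ann, genotypes = geno,
         w = scale(co$truth$A[, co$truth$age_component])[, 1L])
  })
}
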