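Package: methylica
Title: Stability-Clustered ICA of Blood DNA Methylation with Phenotype
    Association, Mediation and Genetic Scoring
Version: 0.1.0
Authors@R:
    person("Methylica", "Developers", email = "methylica@example.org",
           role = c("aut", "cre"))
Description: Decomposes sample-by-CpG DNA methylation beta-value matrices
    into independent components with multi-restart FastICA stabilised by
    icasso-style run clustering, estimates the model order by Random Matrix
    Theory, filters single-individual-dominated components, and links the
    resulting methylation patterns to phenotypes: Pearson association with
    Bonferroni families and double partialling of age, kappa-squared
    mediation with BCa bootstrap, CpG signature extraction with genomic
    context classification and cross-cohort projection, exploratory factor
    analysis of regional cortical thickness, direction-weighted multilocus
    genetic scores with Stouffer meta-analysis, and gene-set enrichment
    corrected for CpG-per-gene bias (Wallenius model) or using
    percentile-cutoff permutation. Includes a synthetic-data generator that
    emulates the statistical structure these analyses assume, so the whole
    pipeline is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
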