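---
title: "Decomposing blood methylomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing blood methylomes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

methylica treats a sample-by-CpG matrix of methylation beta values as a
noisy mixture of a small number of latent *methylomic signatures*. After
covariate adjustment and per-CpG standardization, the residual matrix
$X$ ($n$ samples $\times$ $p$ CpGs) is decomposed as

$$X \approx A\,S,$$

where the rows of $S$ ($k \times p$) are independent, heavy-tailed CpG
loading profiles and the columns of $A$ ($n \times k$) are per-sample
pattern weights. Each column of $A$ is a low-dimensional representation of
a global mode of methylation variation and can be correlated with sample
phenotypes; each row of $S$ defines, through its extreme loadings, the
restricted CpG set that carries the pattern.

The pipeline around the decomposition:

1. **Preprocess** — missing-rate filtering, k-nearest-neighbour
   imputation, optional surrogate-variable estimation, per-CpG OLS
   residualization and standardization.
2. **Decompose** — model order $k$ by Random Matrix Theory; FastICA
   (log-cosh contrast, symmetric fixed-point updates) restarted many
   times; restarts pooled by complete-linkage clustering on
   $1 - |r|$ between mixing columns; each cluster summarized by its
   *centrotype* (the member with maximal summed similarity to its
   cluster); components dominated by single individuals discarded.
3. **Associate** — Pearson tests with explicit Bonferroni families;
   double partialling of age (one age variable removed from the pattern,
   another from the phenotype, since blood draw and assessment happen at
   different times); a nested $F$-test against a fifth-degree age
   polynomial guards against the pattern merely proxying non-linear age.
4. **Mediate** — standardized three-variable mediation with
   $\kappa^2$ effect size and BCa bootstrap intervals.
5. **Signature** — CpGs beyond $n_\sigma$ sd of a component's loading
   distribution; strand-aware TSS/Genic/Intergenic classification;
   projection of a trained component into external cohorts via inverse
   loadings.
6. **Regional EFA** — parallel analysis, principal-axis factoring,
   varimax, Thurstone regression scores predicted into second samples.
7. **Genetic score** — one most significant SNP per gene at a nominal
   threshold, $\pm 1$ direction weights, missingness adjustment, one-sided
   tests, Stouffer meta-analysis, cis-mQTL positional enrichment.
8. **Enrichment** — Wallenius noncentral hypergeometric with a monotone
   probability-weighting function of CpG-per-gene counts; simplified
   percentile-cutoff GSEA with confounder-adjusted gene scores and an
   empirical permutation null.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `max_missing_rate` | 0.05 | CpGs missing in $\ge$ 5% of samples are dropped |
| `k_neighbours` | 10 | KNN imputation neighbourhood |
| `n_sv` | 0 (pipeline), `"auto"` (estimator) | surrogate variables; see below |
| `k` | `"auto"` (RMT) | ICA order: sample-covariance eigenvalues above the Marchenko-Pastur edge $(1+\sqrt{n/p})^2$ |
| `n_restarts` | 30 | ICA restarts pooled by the run clustering |
| `dominance` | 0.10 | max single-sample share of weight variance before a component is discarded |
| `n_sigma` | 4 | signature threshold in sd units (2-3 is typical for expression arrays; methylome-scale data warrants the stringent 4) |
| `n_boot` | 10,000 | BCa bootstrap resamples |
| `p_threshold` | 0.05 | per-SNP selection threshold for the gene score |
| `cis window` | 1 Mbp | cis-mQTL distance |
| GSEA cutoff | 75th percentile | gene-score cutoff for the set statistic |
| set size bounds | 20–200 | genes per analysed set |

Bonferroni families are always explicit arguments (e.g. 15 retained
components, 8 thickness factors) — they are part of the analysis design
and are never inferred from data shape.

## The synthetic world

The generator (`cohort_design()` and friends) states a world rather than
tuning one:

* $n = 300$ young adults (ages uniform 18–35, blood drawn up to ~3.8
  years after assessment), $p = 20{,}000$ CpGs, $k = 5$ components.
* Active loadings are drawn as $\mathrm{sign} \cdot |N(4, 1)|$ on 1% of
  CpGs per component, so the $n_\sigma = 4$ selection rule has a planted
  positive set.
* One component carries the age signal: the correlation targets
  $(r_{\text{age,comp}}, r_{\text{comp,thick}}, r_{\text{age,thick}})
  = (0.29, -0.24, -0.27)$ reproduce the magnitude of the reported
  mediation structure; thickness follows the structural equation
  $y = c'\,\text{age} + b\,\text{comp} + e$ with $c'$ chosen so the
  marginals hit the targets.
* 68 regional thickness measures load 0.7 on 8 orthogonal factors (so the
  factor structure explains ~49% of regional variance, matching the scale
  of real parcellation data); one factor is additionally loaded on the
  mediating component at $r = -0.13$, and episodic memory at $r = -0.138$.
* 53% of SNPs are placed in cis ($\pm$1 Mbp) of the age component's
  active CpGs; those cis SNPs are causal, shifting the component weight
  by `mqtl_effect` (default 0.5 sd) per minor allele via a logistic tilt
  of the allele probability (so a zero effect reduces exactly to
  Hardy-Weinberg draws).
* Betas arise by squashing baseline + signal + noise through the logistic
  map, with baselines from a hypo/hemi/hyper-methylated mixture, which
  reproduces the bimodal marginal distribution of array betas.
* All randomness flows from one integer seed through a counter-based
  splitting scheme (`split_seed()`), so every stage is individually
  reproducible.

**Signal amplitude.** The latent logit-scale signal is multiplied by 0.2
before squashing. This is a realism choice made once: per-CpG methylation
shifts of a few percent are what array studies observe, and they keep the
logistic map effectively monotone-linear. Without damping, loadings of
magnitude 4 times unit-variance weights swing the logit by $\pm 8$,
saturating the map; the resulting nonlinear harmonics carry genuine
above-edge eigenvalues, and RMT (correctly) reports a higher model order
than the planted $k$. A green recovery test therefore establishes that
the estimator recovers *linearly mixed* sparse components — it does not
establish robustness to strong saturation, which no linear decomposition
possesses.

**What the generator does not emulate.** Probe chemistry (detection
p-values, bead counts), realistic LD beyond cis placement, spatial
correlation of neighbouring CpGs, and cell-type deconvolution structure.
Green tests speak to the statistical machinery, not to array artifacts.

## Numerical choices

* **FastICA**: log-cosh contrast, tolerance $10^{-6}$, at most 500
  iterations; whitening is computed once from the eigendecomposition of
  $XX^\top/p$, so restarts differ only in the random orthogonal
  initialisation. Non-converged restarts are excluded with a logged
  count.
* **Sign convention**: each component is oriented to positive loading
  skewness (ties, $|skew| < 10^{-12}$, orient by the largest-magnitude
  loading). Downstream correlations are reported with signs, so a
  deterministic convention is mandatory; recovery checks are sign-blind.
* **RMT with $p < n$**: the roles of $n$ and $p$ swap in the
  Marchenko-Pastur edge — the estimator is symmetric.
* **Varimax**: `stats::varimax` can stall on the symmetric stationary
  point of the unrotated bipolar solution, returning a rotation far from
  the criterion optimum. `fit_efa()` therefore restarts the rotation from
  several fixed orthogonal bases and keeps the best Kaiser-normalized
  criterion value. Factors are ordered by decreasing sum of squared
  loadings and oriented so the largest-loading region is positive.
* **Principal-axis factoring** starts from squared multiple correlations;
  when the correlation matrix is singular (e.g. noiseless factor
  structure) it falls back to the largest absolute row correlation.
  Heywood cases are clipped to 1 with a warning and flagged.
* **Wallenius probabilities** use the exact integral representation under
  the substitution $u = t^{1/D}$, evaluated on the log scale with the
  peak subtracted; the support is renormalized to absorb quadrature
  error. With uniform bias the distribution reduces exactly to the
  central hypergeometric.
* **$\kappa^2$** follows the construction that maximizes $|a|$ and $|b|$
  separately on the positive-semidefiniteness boundary with signs
  matching the observed paths. The known critique — the two maxima are
  not jointly attainable, so $\kappa^2$ is conservative-to-optimistic
  depending on the configuration — is acknowledged; the cited construction
  is what is implemented and tested against a grid oracle.
* **BCa intervals** use the bootstrap-CDF bias correction and jackknife
  acceleration; degenerate resamples (constant columns) are redrawn with
  a logged count and an error past 10%.
* **Tie-breaks**: per-gene SNP selection ties at identical p-values break
  lexicographically by SNP ID; a SNP serving several set genes keeps the
  gene with the stronger signal. Determinism over cleverness.
* **Permutation p-values** are floored at $1/(n_{\text{perm}}+1)$.

## Design choices where the design was open

* **Surrogate estimation** replaces iteratively re-weighted SVA with a
  two-step estimator: residualize against known covariates *and* the
  protected variable, then take leading left singular vectors of the
  residual matrix (count via RMT or user). Surrogates are orthogonal to
  the protected covariate by construction. The estimator cannot
  distinguish genuine sparse latent components from nuisance structure —
  with aggressive `"auto"` settings on the synthetic world it absorbs the
  planted components themselves. The pipeline therefore defaults to
  `n_sv = 0` and leaves surrogate estimation as an explicit choice;
  the reported "40 surrogate variables" of real cohorts is a
  dataset-specific outcome, not a constant of the method.
* **"Inverse loadings"** for cross-cohort projection is implemented as
  the Moore-Penrose pseudo-inverse of the full $k \times p$ loadings
  matrix (the variant that reproduces the training mixing matrix exactly,
  which is the testable property); a single-component mode (loading row
  over its squared norm) is available. Projection targets missing up to
  10% of model CpGs have those CpGs dropped from both sides rather than
  imputed.
* **Projection residuals** are z-scored per CpG before the linear
  combination ("scaled residuals" is read as standardization); the run
  manifest records this.
* **Stouffer weights** default to $\sqrt{n}$; unweighted and
  $n$-weighted variants are selectable because printed meta-analytic
  p-values are reproducible under more than one convention from rounded
  inputs. The weighted mean correlation always uses $n$-weights.
* **Mediation inputs** default to unadjusted variables with covariate
  hooks; the cause is age at the main investigation.
* **Parallel analysis** defaults to 1,000 column-permutation iterations
  at the 95th percentile, counting leading eigenvalues that consecutively
  exceed their null quantile.
* **Likert covariates** (smoking 0-4, alcohol/cannabis 0-2) enter
  association models as numeric scores.
* **Percentile GSEA** reduces the original confounder battery to a
  declared linear adjustment of $-\log_{10} p$ gene scores on supplied
  per-gene properties (length, SNP count, and similar); the statistical
  skeleton — best-SNP score, 75th-percentile cutoff, equal-size random-set
  null, BH FDR — is retained. Random same-size draws are realised
  distribution-exactly.

## Known limitations

* The ICA model assumes a fixed set of linearly mixed independent
  sources; order selection is empirical and the decomposition is only
  identifiable up to sign and permutation.
* The simplified surrogate estimator is a substitute, not a
  reconstruction, of iteratively re-weighted SVA (whose weighting scheme
  is not fully specified in public descriptions).
* Cross-cohort projection assumes the training loadings transfer; the
  package checks CpG overlap but cannot check biological transferability.
* $\kappa^2$ inherits the non-monotonicity critique noted above.
* The enrichment machinery corrects for CpG-per-gene multiplicity and
  declared gene properties only; unmodelled gene-level confounders
  (e.g. recombination structure) are out of scope.

Every empirical number quoted in the package documentation is computed by
the test suite or the acceptance script at run time; none are asserted
from memory.
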