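---
title: "Genetic evaluation of ordinal temperament: models and methods"
author: "docility package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic evaluation of ordinal temperament: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Temperament in beef cattle is routinely recorded as a subjective ordinal
score when yearlings exit a handling chute: 1 (docile) through 6 (very
aggressive).  The distribution is heavily skewed — typically around 72%
of animals score 1 and under 1% score in the top category — and the trait
is influenced by the dam both genetically (maternal genetic effect) and
through the rearing environment (maternal environmental effect).  This
package implements the full evaluation chain for such data: record
editing, contemporary-group construction, Bayesian threshold animal
models, liability-scale heritabilities, forward validation, weighted
correlations between breeding-value sets, and a weighted single-step
GWAS — together with a synthetic-data generator so that every stage can
be exercised and verified without proprietary breed-association data.

## The threshold animal model

Ordinal scores are modelled through a latent Gaussian liability `l`.
For the fullest model,

    l = X b + W w + Z u + Z2 m + S p + e

where `b` are systematic effects (age-of-dam class, conception type
stand-ins, and the age deviation from 365 days as a covariate), `w` is
the contemporary-group (CG) effect with `w ~ N(0, I * var_cg)`, `u` the
direct additive genetic effect, `m` the maternal genetic effect of the
record's dam, `p` the maternal environmental (dam permanent environment)
effect, and `e` the residual.  The genetic effects are jointly
distributed as `(u, m) ~ N(0, Sigma (x) K)`, with
`Sigma = [[var_u, cov_um], [cov_um, var_m]]` and `K` either the pedigree
relationship matrix A or the blended single-step matrix H.  Four nested
models are supported (`model_spec()`): D (direct only), DMG (adds
maternal genetic with the direct-maternal covariance), DMP (adds the
maternal environmental effect) and DMGP (both).  The observed score `c`
arises from thresholds `t`: score `c` when `l` is in
`(t[c-1], t[c]]`.

`fit_threshold_model()` runs a single-site Gibbs sampler written in
C++: liabilities from truncated normals within category bounds, each
location effect from its normal full conditional, the scalar variances
from scaled inverse-chi-squared conditionals, `Sigma` from an
inverse-Wishart, and free thresholds uniformly between the order
statistics of the adjacent categories' liabilities.

### Identification and parameterization

A threshold model's latent scale is arbitrary: one can either fix the
residual variance or fix enough thresholds.  Because liability-scale
residual variances are themselves quantities of interest here, the
package fixes `t1 = 0` and `t2 = 1` and *estimates* the residual
variance (with four categories the remaining threshold `t3` is sampled).
Heritabilities are variance ratios and do not depend on this choice.
With only two categories the scale cannot be separated from the residual
variance, so the binary case fixes `var_e = 1` instead.

### Priors

Defaults are the flat limiting cases: scaled inverse-chi-squared with
`nu = -2`, `scale = 0` for each scalar variance (so the conditional is
`SS / rchisq(n - 2)`), and a zero-scale inverse-Wishart with `nu = 0`
for `Sigma`.  Proper weakly-informative priors are available through
`prior_spec()`.  All priors used are recorded in the fit's metadata.

### Heritabilities

Per retained sample, with `var_t` the model-specific sum of fitted
components (for DMG: `var_u + var_cg + cov_um + var_m + var_e`):

* direct: `hd2 = var_u / var_t`
* maternal: `hm2 = var_m / var_t`
* total: `ht2 = (var_u + 1.5 cov_um + 0.5 var_m) / var_t`

The total heritability weights the maternal terms by the transmitted
fraction; `total_heritability()` gives the closed-form point-estimate
version, e.g. `total_heritability(0.44, 0.04, -0.40)` = 0.3804.

### Convergence diagnostics

`geweke_z()` and `heidel_welch()` are implemented in-package: Geweke's z
compares early/late window means with spectral variances from an AR fit
(`ar()`, density at frequency zero `var_pred / (1 - sum(phi))^2`);
Heidelberger-Welch applies the Cramér-von Mises stationarity test with
iterative 10% discarding, using the asymptotic CvM tail evaluated via
Bessel-K functions.  One numerical rule is worth noting: when the AR fit
of a window is nearly unit-root (`sum(phi) >= 0.97`) the spectral
density estimate diverges and the CvM statistic loses all power, so a
near-unit-root fit is itself treated as a stationarity failure.  A
constant chain is defined to pass with `z = 0`.

The DMGP model is fitted like any other, but with few progeny per dam
the maternal genetic and maternal environmental variances are poorly
separated; the sampler surfaces diagnostics rather than guaranteeing
convergence, and users should inspect them before quoting DMGP
estimates.

## Relationship structures

* `a_matrix()` — dense numerator relationship matrix by the tabular
  method (for moderate pedigrees and oracles).
* `inbreeding()` — Meuwissen-Luo recursion (C++), equal to
  `diag(A) - 1`.
* `a_inverse()` — Henderson's rules *with* inbreeding.  Ignoring
  inbreeding in A-inverse silently corrupts likelihoods in inbred data,
  so the Mendelian-sampling variances use `0.5 - 0.25 (F_s + F_d)`; the
  choice is recorded in the fit metadata.
* `a_subset()` — the A block for the genotyped animals via the
  `T^-1 D T^-T` factorization, avoiding the full dense A.
* `g_matrix()` — `G = R D R' / (2 sum p (1 - p))` with gene content
  centered on observed allele frequencies and a diagonal of marker
  weights D.  The weights deliberately do not enter the denominator, so
  `D = I` reproduces the unweighted G exactly and weighting rescales
  rather than re-normalizes.  Frequencies are fixed at G-build time and
  must be reused when back-solving.
* `h_inverse()` — single-step blending
  `H^-1 = A^-1 + [0 0; 0 (0.90 G + 0.10 A22)^-1 - A22^-1]`, exactly
  A-inverse outside the genotyped block.  No additional tau/omega
  scaling is applied.  A reciprocal-condition-number check reports
  numerically singular blends.

Genotype QC (`genotype_qc()`) removes animals with call rate below 0.90,
then markers with call rate below 0.90, minor allele frequency below
0.01, or an absolute deviation of the observed heterozygote frequency
from `2p(1-p)` above 0.15 (the Hardy-Weinberg screen expressed on the
genotype-frequency scale).  X-chromosome markers are retained only above
the pseudo-autosomal boundary (133,300,518 bp) and are treated as
autosomal thereafter, matching their inheritance.

## LR-method forward validation

`split_partial()` masks the phenotypes of the animals born in the final
year; `lr_metrics()` compares their partial- and whole-data EBVs:
bias `mean(u_p) - mean(u_w)` (the partial-minus-whole sign convention is
fixed and documented), dispersion `cov(u_w, u_p) / var(u_p)` (whole
regressed on partial, expectation 1), and accuracy
`sqrt(cov(u_p, u_w) / ((1 - mean_F) var_u))`, clamped to [0, 1], with
the mean inbreeding of the validation animals in the denominator.  Among
the LR accuracy estimators in use, this covariance form was chosen and
is recorded in the output; it assumes the variance components are well
calibrated, as do all LR summaries.

## Accuracy-weighted EBV correlations

The "approximated genetic correlation" between two traits is the
weighted Pearson correlation of their EBV sets over animals proven in
both.  Two printed-formula ambiguities in the source material had to be
resolved and both resolutions are config-exposed:

* the weight formula as printed reduces to `w = 1` (identical numerator
  and denominator); the package uses `w_i = sqrt(REL1_i * REL2_i)`, the
  natural reading of accuracy-based weights, with `weight_fn` accepting
  any alternative;
* the standard-error formula as printed lacks an exponent; the package
  uses the standard Pearson form `sqrt((1 - r^2) / (n - 2))`, with
  `se_method = "one_minus_r"` available.

Accuracy is the square root of the reliability, and the 0.25 filter is
applied on the accuracy scale, inclusive, for both traits.  Temperament
EBVs are first transformed to the probability of a docile (score 1)
outcome via `docile_probability()` — `pnorm((t1 - ebv)/sigma_e)` — so
the correlated quantity is on the probability scale, with larger values
meaning calmer animals.

## Weighted single-step GWAS

`backsolve_snp_effects()` converts GEBVs of the genotyped animals into
marker effects, `u_hat = k D R' G^-1 gebv`.  Because centering on
observed frequencies makes the all-ones vector a null vector of G, the
solve uses a Moore-Penrose pseudo-inverse; the GEBV mean is the
structural null direction and is legitimately projected out (all window
statistics are invariant to affine shifts of the GEBVs).
`wssgwas_iterate()` starts from identity weights (iteration 1 is the
plain ssGWAS), then derives nonlinear weights
`d = 1.125 ^ (min(|u_std| / sd(u_std), 5) - 2)` from each iteration's
standardized effects (`u_std = u * sqrt(2 p (1 - p))`), rebuilds G with
frequencies held fixed, and re-back-solves; weights are conventionally
reported from iteration 3.  By default the GEBVs are not re-estimated
between iterations (only re-back-solved); a `refit_fn` hook covers the
alternative.

`window_variance()` computes, for every sliding 5-marker window (step
1, never spanning chromosomes), the percentage of the total additive
genetic variance explained, as `100 * var(R_w u_w) / var(R u)` over the
genotyped animals.  Two operationalizations were open and are fixed as
follows: the denominator is the empirical variance of the realized
genomic values (not a sum of `2p(1-p)u^2` terms), and window variances
use realized gene content so within-window LD is captured.  Windows
above 0.20% are flagged, and overlapping flagged windows are merged into
independent regions, each reported with its peak window — the merge rule
("maximal runs of overlapping selected windows, peak per run") is a
package definition since the source material reports non-overlapping
regions without stating one.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults are the
conditions the analysis is meant to face, not tuning knobs:

* sparse maternal families: every female of the previous generation is
  a dam with a zero-truncated Poisson number of progeny, mean 1.6;
* direct heritability near 0.40 with a small maternal genetic component
  (`var_m = 0.04`) negatively correlated with the direct effect
  (`r = -0.40`), a maternal environmental variance of 0.02, a
  contemporary-group variance of 0.10 and residual 0.50;
* a four-category score distribution of 72/22/5/1 percent, realized by
  placing thresholds at the implied normal quantiles of the marginal
  liability;
* genotypes by explicit gene dropping from founder haplotypes (allele
  frequencies uniform on the configured MAF range), so realized genomic
  relationships agree in expectation with the pedigree A — a property
  the single-step machinery relies on and multivariate-normal genotype
  shortcuts would break;
* a small X-labelled marker block entirely above the pseudo-autosomal
  boundary, simulated with autosomal inheritance (which is how
  pseudo-autosomal markers behave);
* fixed effects limited to an intercept, one 3-level categorical factor
  and one covariate — enough to test estimability without replicating
  breed-association effect codings.

Markers segregate independently by default (linkage equilibrium).  An
optional founder-haplotype block-copy scheme (`ld_blocks = TRUE`)
induces within-block LD, with no claim of matching any real LD decay.
Prediction errors in `simulate_ebv_pairs()` are correlated across the
two traits at the true-value correlation, emulating a joint evaluation
in which the error covariance follows the genetic covariance; with
independent errors the EBV correlation would be attenuated by roughly
the mean accuracy product and could not recover the generating
correlation even in principle.

What passing tests on these data do **not** show: robustness to real LD
structure, genotype imputation error, non-random use of sires,
selection, or the confounding between embryo-transfer calves and
recipient dams.  The generator deliberately excludes all of these.

## Problem sizes used in the validation suites

The package's property suites run at sizes chosen to make the checks
statistically meaningful while staying desk-scale: heritability recovery
uses pedigrees of about 4,900 animals (1,700 founders, 3 generations,
roughly 3,200 phenotyped) with 20 replicate datasets and 20,000 Gibbs
iterations each (10,000 burn-in, thinning 10); LR validation uses ten
replicates of about 2,900-animal pedigrees with variance components
fixed at their generating values, as production validation runs fix
them; the marker-level checks use a few hundred to 1,500 animals and
50-2,000 unlinked markers.  At these sizes the heritability-recovery
suite observes |bias| well under 0.05 with interval coverage at or above
0.90, and the disjoint-window variance decomposition reconstructs the
genomic variance within a few percent.

## Known limitations

* Single-trait models only; the correlation module approximates genetic
  correlations from EBVs rather than estimating them jointly.
* Reliabilities are PEV-based (`1 - PEV / var_u_hat`), a different
  approximation than production software that propagates contribution
  counts; they are used for weighting and filtering, not certification.
* The DMGP model is frequently unidentifiable in data with ~1.6 progeny
  per dam; that is a property of the design, not of the sampler.
* Chromosome labels sort lexicographically in the marker map; numeric
  labels above 9 should be zero-padded if mixed with single digits.
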