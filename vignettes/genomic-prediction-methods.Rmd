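---
title: "Single- and multi-trait Bayesian genomic prediction for dairy traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single- and multi-trait Bayesian genomic prediction for dairy traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mtgblup` implements a genomic-prediction workflow for dairy cattle milk
traits — 305-day milk yield (MY, kg) and the fat, protein, lactose and dry
matter percentages (MF, MP, ML, MDM) — from SNP dosage data of genotyped
cows. It covers genotype quality control, the VanRaden genomic relationship
matrix, single-trait (ST) and multi-trait (MT) Bayesian ridge-regression
models fitted by Gibbs sampling, posterior heritabilities and genetic
correlations computed from marker-effect draws, and hold-out validation
(accuracy, dispersion bias, marker-effect rank correlations). A seeded
synthetic dairy-population generator with recorded truth makes every stage
testable without access to proprietary milk-recording data.

Only genotyped animals enter the model: relationships come from markers
alone, with no pedigree blending.

# Models

## Single-trait model

For one trait on the training animals,

$$y = Xb + Wd + M\alpha + e,$$

where $X$ is the fixed-effect incidence (intercept plus treatment-coded
dummies for lactation order, levels 1–3, and farm, levels 1–12), $W$ the
incidence of days-in-milk (DIM) classes, $M$ the allele-frequency-centered
dosage matrix, and

$$\alpha_j \sim N(0, \sigma_\alpha^2) \;\; \text{iid}, \quad
  d_l \sim N(0, \sigma_d^2) \;\; \text{iid}, \quad
  e \sim N(0, \sigma_e^2 I).$$

The induced genetic values $g = M\alpha$ satisfy
$\operatorname{Var}(g) = MM^\top \sigma_\alpha^2 = cK\sigma_\alpha^2$ with
$K = MM^\top / c$, $c = 2\sum_j p_j(1-p_j)$ — i.e. this is the marker-effect
(SNP-BLUP) parameterization of GBLUP with genetic variance
$\sigma_a^2 = c\,\sigma_\alpha^2$. We work in the marker parameterization
because the genetic covariance estimator below consumes per-iteration marker
effects directly; the test suite verifies the equivalence against a direct
mixed-model (GLS) solve.

## Multi-trait model

For $t$ traits jointly, each marker carries a $t$-vector of effects

$$a_i \sim N(0, \Sigma_\alpha), \qquad
  e_{\text{row}} \sim N(0, R),$$

with unstructured $\Sigma_\alpha$ (genetic, marker scale) and $R$
(residual). The induced genetic values have the Kronecker covariance
$\Sigma \otimes K$ of multi-trait GBLUP. DIM class effects are independent
across traits (diagonal covariance): DIM is a nuisance term and an
unstructured DIM covariance would not be identifiable from ~12 classes.
The grand mean is absorbed into the intercept column of $X$.

## Gibbs sampler

Both samplers are written in C++ (RcppArmadillo) and draw, per iteration and
in fixed order:

1. fixed effects jointly from their (matrix-)normal full conditional, flat
   prior — the conditional mean is the OLS projection of the current partial
   residuals;
2. each DIM class effect (ST: scalar normal; MT: a $t$-variate normal
   coupled through $R^{-1}$);
3. each marker effect by single-site (coordinate) updates with running
   residual updates, $O(n\,p\,t)$ per iteration;
4. variance components from their conjugate full conditionals —
   scaled-inverse-$\chi^2$ (ST) or inverse-Wishart (MT).

All randomness flows through R's RNG, so a seeded fit is bit-reproducible;
the suite asserts this for every stage.

## Priors

Variance components get weakly informative conjugate priors whose *mode*
splits the observed phenotypic variance as 30% genetic, 5% DIM, 65%
residual (`var_split` in `chain_config()`): scaled-inverse-$\chi^2$ with
$\nu = 5$ in the single-trait model, inverse-Wishart with
$\nu = t + 3$ and diagonal scale in the multi-trait model. These mirror the
defaults of the Bayesian regression software commonly used for this class
of analysis. Fixed effects carry flat priors. Note that these prior
families are strongly right-skewed: their mean is 2.3× (ST) to 7× (MT,
$t=5$) their mode, which matters for weakly identified variance components
(see *Limitations*).

## Genetic parameters from marker-effect draws

At each retained iteration $k$, the genetic covariance between traits is
accumulated from the sampled marker effects:

$$\sigma_g^{(k)} = \sum_{i=1}^{p} \operatorname{var}(\text{SNP}_i)\,
  a_i^{(k)} a_i^{(k)\top},$$

with $\operatorname{var}(\text{SNP}_i)$ the empirical dosage variance of
marker $i$ (denominator $n$) on the training animals. The posterior mean
over retained draws is the point estimate; genetic correlations are
computed per draw as
$\sigma_{g,12}/\sqrt{\sigma_{g,11}\sigma_{g,22}}$ and averaged, so every
reported correlation is an average of quantities bounded in $[-1, 1]$.
Heritability per draw is

$$h^2_t = \frac{\sigma_{g,tt}}{\sigma_{g,tt} + \sigma_{d,t}^2 + R_{tt}},$$

with the DIM variance included in the denominator because DIM is a random
model term (excluding it would inflate $h^2$; `include_dim = FALSE`
disables this). The reported standard error is the posterior standard
deviation across retained draws. Phenotypic correlations are pairwise
Pearson correlations on the raw trait values — the model-adjusted
alternative is deliberately not the default, since covariate-adjusted and
raw phenotypic correlations answer different questions and the raw version
requires no model.

## Validation

A single random hold-out split (default 400 training / remaining ~97
validation animals) mirrors standard practice for this design. Accuracy is
the Pearson correlation between observed phenotypes and GEBVs in the
validation set; bias is the slope of the regression of phenotype on GEBV,
with slopes above one indicating under-dispersed (underestimated) GEBVs —
regressing in this direction is the only one under which that reading is
coherent. An `adjusted = TRUE` option correlates GEBVs with fixed-effect
residuals instead of raw phenotypes. Marker-effect rank correlations use
squared posterior-mean effects by default (the scale on which per-marker
effects are usually displayed), with average-rank ties and t-approximation
p-values; absolute and raw scales are available.

# The synthetic dairy population

`sim_config()` defaults describe a post-QC Polish Holstein-Friesian-like
milk-recording dataset: 497 cows on 12 farms, lactation orders 1–3, DIM
uniform on 5–360 days binned into 30-day classes (matching the monthly
recording rhythm), 2000 independent biallelic markers with allele
frequencies uniform on (0.05, 0.5), 1% genotype missingness, and the five
milk traits with heritabilities (0.2424, 0.2223, 0.3029, 0.2171, 0.2437)
and a weak genetic correlation matrix whose largest entry is MF–MDM at
0.499. Trait means and SDs (8000±1200 kg; 4.10±0.55, 3.35±0.30, 4.85±0.20,
13.0±0.90 %) are typical lactation-average values for this breed. Farm and
lactation effects are drawn with SDs of 0.25 and 0.15 phenotypic SDs; the
DIM classes carry 5% of phenotypic variance.

Residual correlations default to the *genetic* correlation matrix. This is
a deliberate simplification: with heritabilities near 0.22 and genetic
correlations near 0.5, strong phenotypic correlations (e.g. fat–dry matter
above 0.9, as seen in real milk composition data) would require residual
correlations above 1 and are therefore not reproducible in this variance
decomposition; the generator targets the *genetic* regime and realistic
variance fractions rather than the full phenotypic correlation surface.

True marker effects are drawn iid
$a_i \sim N(0, \Sigma_g^{\text{target}}/\sum_i \operatorname{var}(\text{SNP}_i))$,
so the marker-effect genetic covariance matches its target in expectation;
the generator records realized heritabilities and genetic correlations next
to every dataset. Markers are unlinked by default — the inference model
nowhere exploits LD, and independence makes the realized-parameter oracles
exact in expectation. An optional Gaussian-copula block-LD mode
(`ld_rho`, `ld_block_size`) exists for sensitivity checks but is off by
default. The generator does not emulate pedigree structure, selection,
drift, or chip ascertainment — passing tests say nothing about those
features of real data.

# Numerical choices

- **QC order and strictness.** Animals are filtered first (missing rate
  strictly above 10% removed), MAF is then recomputed on the retained
  animals and markers kept only if MAF is strictly greater than 5% (which
  removes monomorphic markers), and remaining missing dosages are
  mean-imputed, which preserves allele frequencies. A second QC pass is a
  no-op, and the suite asserts it.
- **GRM.** VanRaden's first construction with observed allele frequencies
  and a single scaling constant $c = 2\sum p_j(1-p_j)$; an optional
  $10^{-8}$ diagonal jitter guards factorizations. No blending toward the
  identity.
- **Centering for prediction** uses training-set allele frequencies for all
  animals; the per-marker shift is constant across animals, so validation
  accuracy and bias are unaffected by this choice.
- **DIM classes** are 30-day bins, `floor((dim - 1)/30) + 1`.
- **Degenerate inputs** error early and name the offender: fully missing
  markers at imputation, rank-deficient fixed-effect incidence, marker-panel
  mismatches at prediction, empty animal intersections at alignment.
- **Chain lengths.** The package default is 100,000 iterations with 20,000
  burn-in and thinning 10. The test suite and the acceptance script run
  desk-scale chains (3,000 iterations, 1,000 burn-in, thin 5, and
  20,000-draw chains on 30×50 fixtures for the closed-form comparisons),
  with problem sizes of 400–500 animals and 1,000–2,000 markers.

# Limitations

- **Weak identification of $h^2$ at $p \gg n$.** With ~400 training animals
  and 2,000 unlinked markers, the likelihood separates genetic from
  residual variance only weakly (posterior SD of $h^2$ around 0.1). In that
  regime the right-skewed conjugate priors pull the posterior mean of
  $h^2$ upward of the simulated truth by roughly +0.05 to +0.15 for traits
  with true $h^2 \approx 0.22$. This is a property of the exact posterior,
  not of the sampler: a grid-evaluated eigendecomposition oracle for the
  marginalized two-variance model reproduces the same posterior means, and
  the same sampler recovers $h^2$ without bias when $n > p$. Users should
  read reported heritabilities at this scale as posterior summaries under
  these priors, not as unbiased point estimates; genetic correlations and
  GEBV accuracies are much less affected.
- **Small multi-trait gains at desk scale.** With unlinked markers and a few
  hundred training animals, per-trait GEBV accuracies sit near 0.1 and the
  expected multi-trait minus single-trait accuracy gain for a correlated
  low-heritability trait is of order +0.005 — below the Monte-Carlo noise of
  a handful of hold-out replicates. The package's multi-trait machinery is
  therefore validated primarily through the deterministic equivalences
  (ridge/GBLUP/mixed-model solves) and genetic-correlation recovery, not
  through accuracy differences, which at this scale fluctuate around zero.
- **Genotyped-only relationships.** No pedigree, hence no single-step
  H-matrix; ungenotyped ancestors contribute nothing.
- **Complete-case multi-trait training.** Animals missing any trait are
  dropped from the MT fit rather than handled by data augmentation.
- **No variable selection.** The ridge (equal-variance) prior is the only
  marker prior; Bayes A/B/C-type mixtures are out of scope, as are REML
  fits and multi-environment extensions.

# Reproducibility

Every stochastic stage accepts a seed; `run_validation()` derives
independent sub-seeds for the split and each chain from its master seed.
`write_manifest()` fingerprints artifacts (MD5) so two seeded runs can be
compared bit-for-bit; the suite asserts manifest equality end-to-end. The
`inst/cli/mtgblup.R` script exposes `simulate` and `validate` subcommands
over these functions, and `scripts/acceptance.R` re-runs the full pipeline
from scratch and emits its headline numbers as JSON.
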