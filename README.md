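# mtgblup

Single- and multi-trait Bayesian genomic prediction for dairy cattle milk
traits, for quantitative geneticists and breeding-program analysts working
with genotyped cows only (no pedigree).

The package takes an animals × markers SNP dosage matrix (TSV or VCF) and a
phenotype table with five traits — 305-day milk yield (MY, kg) and milk fat,
protein, lactose and dry-matter percentages (MF, MP, ML, MDM) — plus
lactation order, farm and days in milk (DIM), and provides:

- **Genotype QC** — animals with missing rate > 10% removed, markers kept
  only if MAF > 5% (monomorphic markers removed), residual missing dosages
  mean-imputed;
- **Genomic relationship matrix** — VanRaden's
  $K = MM^\top / c$, $c = 2\sum_j p_j(1-p_j)$, from frequency-centered
  dosages $M$;
- **Gibbs-sampled marker-effect models** (RcppArmadillo) — single-trait
  $y = Xb + Wd + M\alpha + e$ with $\alpha_j \sim N(0,\sigma_\alpha^2)$,
  equivalent to GBLUP with $\mathrm{Var}(g) = K\,c\,\sigma_\alpha^2$; and a
  multi-trait version with per-marker effect vectors
  $a_i \sim N(0, \Sigma_\alpha)$ and unstructured residual covariance $R$,
  inducing the $\Sigma \otimes K$ genetic covariance. Fixed lactation-order
  and farm effects, random 30-day DIM classes, conjugate
  scaled-inv-$\chi^2$ / inverse-Wishart variance priors;
- **Genetic parameters from marker-effect draws** — per retained iteration
  $\sigma_g^{(k)} = \sum_i \mathrm{var}(\mathrm{SNP}_i)\, a_i^{(k)} a_i^{(k)\top}$,
  giving posterior heritabilities $h^2_t = \sigma_{g,tt}/(\sigma_{g,tt} +
  \sigma^2_{d,t} + R_{tt})$ with posterior-SD standard errors, and genetic
  correlations $\sigma_{g,12}/\sqrt{\sigma_{g,11}\sigma_{g,22}}$ averaged
  over draws;
- **Validation** — seeded hold-out split (e.g. 400 train / 97 test),
  accuracy $r = \mathrm{cor}(y_{\text{obs}}, \mathrm{GEBV})$, dispersion
  bias $b$ (slope of phenotype on GEBV; $b > 1$ = underestimation), the
  MT−ST accuracy difference per trait, and Spearman rank correlations of
  squared marker effects between traits;
- **A synthetic dairy-population generator** with recorded truth
  (497 cows, 12 farms, 3 lactation orders, 2000 markers by default,
  heritabilities ≈ 0.22–0.30, weak genetic correlations with MF–MDM ≈ 0.5)
  so the whole pipeline is testable end to end.

See `vignettes/genomic-prediction-methods.Rmd` for the models, priors,
numerical choices and limitations.

## Worked example

```r
library(mtgblup)

# a seeded synthetic herd with known truth
cfg <- sim_config(seed = 1)              # 497 cows x 2000 markers, 5 traits
sim <- simulate_dataset(cfg)

run <- run_validation(
  sim$geno, sim$pheno,
  chain = chain_config(n_iter = 3000, burn_in = 1000, thin = 5, seed = 1),
  n_train = 400
)
print(run$results[, c("trait", "r_mt", "r_st", "accuracy_diff")])
print(run$params$h2)
```

On this seed the run prints (values rounded):

```
  trait   r_mt   r_st accuracy_diff
     MY  0.138  0.172        -0.034
     MF  0.070  0.082        -0.011
     MP  0.155  0.178        -0.023
     ML -0.043 -0.063         0.020
    MDM -0.012 -0.064         0.052
```

with posterior heritabilities `MY 0.279, MF 0.338, MP 0.377, ML 0.339,
MDM 0.312` (true values 0.24–0.30) and a posterior MF–MDM genetic
correlation of 0.35 (truth 0.50). Accuracies near 0.1 are the expected
ceiling for this synthetic regime: with 2000 *unlinked* markers and 400
training animals, cor(phenotype, GEBV) ≈ h·r(g, ĝ) ≈ 0.1 — real SNP panels
predict far better because linked markers shrink the effective number of
independent segments. Heritabilities at this scale are weakly identified
and read high against the simulated truth; the vignette's *Limitations*
section quantifies this.

At production scale, chains run 100,000 iterations with 20,000 burn-in
(`chain_config()` defaults, or `--full-scale` in the CLI). A thin
command-line front-end lives at `inst/cli/mtgblup.R`:

```sh
Rscript inst/cli/mtgblup.R simulate --out data/ --seed 1
Rscript inst/cli/mtgblup.R validate --geno data/genotypes.tsv \
    --pheno data/phenotypes.csv --out results/ --seed 1
```

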