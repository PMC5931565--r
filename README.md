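# gallop

Fast genome-wide association analysis of **longitudinal phenotypes** — traits
measured repeatedly over time on the same unrelated individuals.

## The problem and the method

The standard analysis fits, for every SNP, the linear mixed model

```
y_ij = β0 + β1·t_ij + β2·SNP_i + β3·t_ij·SNP_i + C_ij·βcov + b0_i + b1_i·t_ij + ε_ij
```

with per-subject random intercept and slope `b_i ~ N(0, D)` and errors
`ε_ij ~ N(0, σ²)`. β2 is the cross-sectional SNP effect (level shift), β3
the longitudinal effect (change of slope over time) — usually the effect of
interest. Refitting this mixed model per SNP re-estimates `(D, σ²)` millions
of times, which is what makes longitudinal GWAS slow.

This package estimates `(D, σ²)` **once**, on the SNP-free reduced model
(REML via lme4), and then solves each per-SNP fit exactly as a penalized
least-squares problem — Henderson's equations with penalty
`P* = (D/σ²)⁻¹` — whose system matrix differs between SNPs only in the two
bordering rows and columns the SNP contributes. A one-time per-subject
whitening (`Φ_i(S_i + P*)Φ_iʹ = I`) and a factorized core matrix reduce each
SNP to a 2×2 solve

```
C = Σ s_i²F_i − aM⁻¹aʹ,   a = Σ s_i E_i,   β̂snp = C⁻¹ Σ s_i g_i,
SE = σ̂·sqrt(diag C⁻¹)
```

fed by two weighted aggregations (weights `s` and `s²`) of small per-subject
feature vectors — the genotype vector is never expanded across measurement
occasions. The result is algebraically identical to the exact full solve at
the fixed variance components (the test suite pins it at 1e-8 relative), and
p-values for truly associated SNPs are conservative, never anti-conservative,
because omitted SNP effects inflate the reduced-model variances.

Intended users: statistical geneticists running longitudinal GWAS on
cohort data (dosage matrices from imputation), and anyone needing exact
penalized mixed-model solves with a fast per-covariate border update.

## Worked example

```r
library(gallop)
set.seed(2024)

cfg <- sim_config(n = 500)                       # longitudinal GWAS generator
sim <- simulate_dataset(cfg, beta2 = 0.5, beta3 = 0.3, m = 2000)

gd  <- assemble_longitudinal(sim$pheno, covariates = c("cov1", "cov2", "cov3"))
fit <- fit_variance_components(gd)               # REML, SNP-free reduced model
fit
#> Reduced-model REML fit (random intercept + slope)
#>   D (random-effect covariance):
#>           intercept   slope
#> intercept    0.6067 -0.1168
#> slope       -0.1168  1.1405
#>   residual sigma: 2.5172
#>   fixed effects:
#> (Intercept)        time        cov1        cov2        cov3
#>     -2.9486     -1.6885      0.0936     -0.6222      1.1359

pc  <- gallop_precompute(gd, fit)                # one-time, shared by all SNPs
res <- gallop_score(pc, sim$dosage)              # 2000 SNPs in ~0.3 s
head(res[, c("snp", "beta_cs", "se_cs", "p_cs", "beta_long", "se_long", "p_long")], 3)
#>    snp     beta_cs  se_cs        p_cs  beta_long se_long     p_long
#> 1 snp1  0.68041229 0.2270 0.002727663 0.19619914 0.09337 0.03561224
#> 2 snp2 -0.22402790 0.2125 0.291807948 0.02193263 0.08971 0.80686364
#> 3 snp3 -0.08739075 0.2207 0.692070914 0.09218874 0.09207 0.31668086
```

`snp1` is the causal SNP (true β2 = 0.5, β3 = 0.3): its level effect is
estimated at 0.68 ± 0.23 (p ≈ 0.003) and its slope effect at 0.20 ± 0.09
(p ≈ 0.036); the other SNPs are null and behave accordingly. Each row also
carries `n_used`, `freq` (mean dosage / 2) and a `status` flag
(`ok`, `imputed`, `monomorphic`, `skipped`, `unstable`).

For file-based genome-wide scans use `gallop_run()` (phenotype TSV in,
chunked text or flat-binary dosage store in, results TSV + run-metadata JSON
out), or the command-line wrapper:

```sh
Rscript inst/cli/gallop.R --pheno pheno.tsv --geno dosages.bin \
    --out results.tsv --chunk-size 1000 --oracle 7.05
```

`--oracle 7.05` re-checks every hit above that −log10 p with the exact
per-SNP solver. `score_snp_exact()` / `henderson_solve()` expose that exact
path directly, and `run_accuracy_study()` reproduces the fast-vs-refit
calibration experiment on simulated data.

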