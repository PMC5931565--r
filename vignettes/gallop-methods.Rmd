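---
title: "Fast longitudinal GWAS by bordered penalized least squares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast longitudinal GWAS by bordered penalized least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gallop)
```

## The model and the computational problem

For a phenotype measured repeatedly on $n$ unrelated individuals, the
standard per-SNP analysis fits the linear mixed model

$$
y_{ij} = \beta_0 + \beta_1 t_{ij} + \beta_2\,\mathrm{SNP}_i
       + \beta_3\, t_{ij}\,\mathrm{SNP}_i + C_{ij}\beta^{\mathrm{COV}}
       + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij},
$$

with per-subject random intercept and slope $b_i \sim N(0, D)$ and
independent errors $\varepsilon_{ij} \sim N(0, \sigma^2)$. The
cross-sectional effect $\beta_2$ shifts the level of the trait; the
longitudinal effect $\beta_3$ changes its rate of change. Fitting this model
separately for each of millions of SNPs is dominated by re-estimating the
variance components $(D, \sigma^2)$ every time, which is wasteful: a single
SNP explains so little variance that the components barely move.

This package fixes $(D, \sigma^2)$ at their REML estimates from the
*reduced* model (the same model without the SNP terms), after which every
per-SNP fit is an exact penalized least-squares problem — Henderson's mixed
model equations with penalty $P^{*} = (D/\sigma^2)^{-1}$ — whose system
matrix changes only in the two bordering rows and columns contributed by the
SNP. The border is exploited as follows.

1. **Whitening.** The random-effect block of the reduced system is block
   diagonal with $2\times 2$ blocks $S_i + P^{*}$, where
   $S_i = Z_i' W_i Z_i$ and $Z_i = [\,1\;\, t_i\,]$. From the
   eigendecomposition $U_i \Omega_i U_i'$ of each block we form
   $\Phi_i = \Omega_i^{-1/2} U_i'$, so that
   $\Phi_i (S_i + P^{*}) \Phi_i' = I$. Eigenvalues are taken in ascending
   order and eigenvector signs are unconstrained; results are invariant
   because $\Phi_i$ only enters through $\Phi_i'\Phi_i = (S_i+P^{*})^{-1}$.
2. **One-time features.** With $K_i = \Phi_i S_i$,
   $\tilde A_i = \Phi_i R_i$ ($R_i = Z_i'W_iX_i^{*}$) and the reduced-model
   solution $(\beta^{*}, \theta)$, each subject contributes three small
   border features: $E_i = R_i - K_i'\tilde A_i$ ($2 \times p$),
   $F_i = S_i - K_i'K_i$ ($2\times 2$) and
   $g_i = r_i - R_i\beta^{*} - K_i'\theta_i$ (length 2). The core matrix
   $M = A_{11} - \sum_i \tilde A_i'\tilde A_i$ is factorized once.
3. **Per-SNP solve.** Because a dosage $s_i$ is constant over a subject's
   occasions, the SNP columns never need to be expanded across rows: the
   whole bordered system collapses, by a Schur complement, to the
   $2 \times 2$ solve
   $$
   C = \textstyle\sum_i s_i^2 F_i - a M^{-1} a', \qquad
   a = \textstyle\sum_i s_i E_i, \qquad
   \hat\beta^{\mathrm{SNP}} = C^{-1} \textstyle\sum_i s_i g_i,
   $$
   with standard errors $\hat\sigma\sqrt{\operatorname{diag}(C^{-1})}$. For
   a block of $m$ SNPs all three aggregations are two cross products of the
   $n \times m$ dosage matrix (weights $s$ and $s^2$) against stacked
   feature matrices, so memory is $O(nm + np)$ and a genome-wide scan is a
   sequence of dense matrix products.

The identical algebra is available through the exact solver
(`henderson_solve()` / `score_snp_exact()`), which assembles and solves the
full sparse $(p + 2 + 2n)$-dimensional system. The test suite pins the fast
path to this oracle at $10^{-8}$ relative for every coefficient and standard
error; the equivalence is algebraic, so it holds for any effect size.

## What the approximation costs

Fixing $(D, \sigma^2)$ at the reduced-model estimates is the method's only
approximation. When a SNP truly has effects $(\beta_2, \beta_3)$, the
reduced model absorbs them into the random effects, inflating their
covariance to approximately

$$
D^{*} = D + \mathrm{var}(\mathrm{SNP})
\begin{pmatrix} \beta_2^2 & \beta_2\beta_3 \\ \beta_2\beta_3 & \beta_3^2 \end{pmatrix},
$$

implemented in `variance_inflation()` and verified by simulation. Inflated
variances mean inflated standard errors, so p-values for truly associated
SNPs are *conservative*, increasingly so for larger effects — a one-sided
error that cannot create false positives. At a truly null SNP the reduced
and full fits differ only through two fixed-effect degrees of freedom and
agreement is essentially exact (the suite checks $-\log_{10}p$ agreement to
0.01 at the null grid point). At moderate effects the conservative gap is
measurable: an SE inflation of 0.5% already costs $z^2\delta/\ln 10 \approx
0.1$ in $-\log_{10}p$ at $z \approx 5$. The practical recipe is the one the
accuracy study quantifies: scan with a slightly relaxed threshold, then
re-check candidate hits with a full refit (`gallop_run(oracle_mlp = ...)`).

p-values use the standard-normal Wald reference throughout. At GWAS sample
sizes the difference from a $t$ reference is negligible, and it makes the
fast path and the refit comparator directly comparable.

## Variance-component estimation

The reduced model is fitted by REML through `lme4::lmer`, the standard tool
for exactly this fit; an independent implementation (`nlme::lme`) serves as
a cross-check in the test suite, and the package's own whitened solver
reproduces lmer's fixed and random effects at the fitted components to
$10^{-9}$. Two numerical details matter:

* **False boundary optima.** lme4's default optimizer occasionally collapses
  the random-intercept variance to zero at a local optimum whose REML
  criterion is demonstrably worse than the interior solution. When a fit
  comes back singular or nearly so (smallest eigenvalue of $\hat D$ below 1%
  of the largest), the fit is retried with `bobyqa` and the lower-criterion
  solution kept.
* **Genuine boundary fits.** If the best fit still has singular $\hat D$,
  the penalty $P^{*}$ is undefined; the fit is flagged and
  `gallop_precompute()` refuses it rather than silently regularizing. With
  the study's generative values this happens for small samples (a few
  hundred subjects) because the intercept variance is weakly identified when
  all measurements lie far from $t = 0$ against a residual SD of 2.5; it was
  not observed at $n \ge 500$.

Subjects with a single observation are retained: $S_i$ is then singular but
$S_i + P^{*}$ remains positive definite, and the whitening identity holds
unchanged (covered by a dedicated test).

## Missing data

Phenotype rows with a missing outcome, time or covariate receive weight 0
and are zeroed, which makes every weighted cross product identical — to
summation order — to the same product over a physically row-deleted dataset;
the suite asserts end-to-end agreement at $10^{-10}$ relative. Subjects left
with no valid row are dropped. A `strict` policy errors instead, for
pipelines that prefer explicit cleaning. Missing genotype dosages are either
mean-imputed per SNP (the default; the SNP is flagged) or the SNP is left
unscored. Monomorphic SNPs (dosage variance below $10^{-8}$) and bordered
systems with condition number above $10^{12}$ are flagged, not scored.

## The synthetic-data generator

`sim_config()` defaults encode the generative design used for calibration
throughout: $n = 2000$ subjects, $k = 4$ occasions at times uniform on
$(0, 10)$; three time-varying covariates $\sim N(2, \mathrm{sd}\,0.5)$ with
coefficients drawn once per dataset from $N(0,1)$; $\beta_0 = -2.6$,
$\beta_1 = -1.9$; $D = [[1, -0.2], [-0.2, 1]]$; $\sigma = 2.5$; continuous
dosages uniform on $(0, 2)$ (the imputed-genotype convention; a
`binomial` hard-call option exists). Effect grids place $\beta_2$ and
$\beta_3$ on 200 equally spaced values in $[0, 1]$; the accuracy study pairs
the two grids as independent random permutations, one dataset per pair,
because the joint layout of the two grids is otherwise underdetermined. The
covariate spread is read as an SD (switchable via `cov_par_is_sd`).

The generator emulates the statistical structure that matters for the
method — subject-constant dosages, linear time trends, exchangeable
occasions, MCAR missingness via `inject_missingness()` — and deliberately
not the features of real cohorts that are orthogonal to it: linkage
disequilibrium between SNPs, population structure and relatedness,
informative dropout, non-linear trajectories, heteroscedastic or
autocorrelated errors. Passing tests therefore demonstrate computational
correctness and calibration under the model's own assumptions, not
robustness to their violation.

## The accuracy study and its two headline numbers

`run_accuracy_study()` simulates one causal SNP per dataset over the effect
grid, scores it with the fast path, refits the full model by REML
(`lme4`, normal Wald p-values) as the exact comparator, and records both
estimate sets, both p-values, the per-replicate variance components, and
predictive $R^2 = 1 - \lVert y-\hat y\rVert^2 / \lVert y-\bar y\rVert^2$
for the full and reduced models. Two fitted-value conventions are recorded,
because they answer different questions:

* *marginal* ($\hat y = X\hat\beta$): the population-level fit; the
  difference full-minus-reduced is the usual GWAS notion of variance
  explained by the SNP terms, reaching about 22–25% at the top of the effect
  grid in this design (theory:
  $\mathrm{var}(\beta_2 s + \beta_3 st)/\mathrm{var}(y) \approx 23/92$ at
  $\beta_2 = \beta_3 = 1$);
* *conditional* ($\hat y = X\hat\beta + Z\hat b$): the subject-level fit;
  here the reduced model's BLUPs absorb nearly all of a subject-constant
  SNP effect (slope absorption is about 95% in this design), so the
  difference stays below 0.01%.

The study reports the marginal difference as "the SNP contribution". We note
candidly that neither convention reproduces a mid-single-digit contribution
at the top of this effect grid; a value near 6% arises marginally at
$(\beta_2, \beta_3) \approx (1, 0.5)$, i.e. for a smaller interaction
effect. Both variants are kept in the report so the reader can apply either
definition.

`threshold_calibration()` computes $\tau$: the smallest fast-path
$-\log_{10}p$ among all pairs whose refit $-\log_{10}p$ exceeds a cut
(genome-wide 7.3). Scanning at $\tau$ and refitting hits loses no
refit-significant SNP. At the full 200-replicate design $\tau$ lands a
little above 7 (the conservative gap at the cut is roughly 0.1–0.3). At
reduced replicate counts the raw minimum is upward-biased because few pairs
land just above the cut — grid spacing near $-\log_{10}p = 7.3$ is 0.5–1
per grid step — so the 50-replicate suite additionally interpolates the
conservative gap at the cut to estimate the dense-grid threshold.

## Problem sizes and numerical choices

The suite runs the oracle-equivalence check at $n = 500$ with 200 SNPs, the
null-calibration check on 5000 null SNPs at $n = 1000$ (type-I error inside
the 99% binomial band at $\alpha = 0.05$, Kolmogorov–Smirnov uniformity),
the accuracy study at 50 replicates of the full $n = 2000$ design, and
parameter recovery at the design's own 200 replicates; these sizes make the
whole suite run in about a minute while keeping every check at the study's
stated $n$. Cholesky factorization is used for the core matrix $M$ (refusing
non-PD inputs, which indicate collinear covariates), closed-form
eigendecomposition for the $2\times2$ whitening, and a single sparse
factorization per exact solve. Chunked scoring defaults to 1000 SNPs per
block; results are invariant to chunk size and to subject permutation, and
the binary dosage container stores each SNP contiguously so a chunk is one
contiguous read, with a JSON sidecar declaring layout, identifiers and the
missing-value sentinel.

## Known limitations

Beyond the generator's stated scope: no kinship or repeated-structure
between subjects (individuals must be unrelated); exactly two random effects
(intercept and slope — no higher-order time trends); homoscedastic
independent errors; dosage coding is additive only. Wall-clock speed-ups
relative to per-SNP refitting depend on hardware and on genotype storage
layout and are therefore demonstrated, not asserted, by the timing-free
equivalence and calibration tests here.
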