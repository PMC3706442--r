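---
title: "Models and methods in genarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in genarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genarch)
```

genarch estimates genetic influence on a longitudinally measured
quantitative trait in three complementary ways — twin variance
components, SNP heritability from unrelated individuals, and a
genome-wide association scan — together with the quality control,
phenotype transformations and power analysis that a complete analysis
needs. This vignette is the package's own account of the models, the
numerical choices behind them, and what the synthetic-data generator
does and does not emulate.

## The twin model

For a standardized phenotype, co-twin resemblance decomposes into
additive genetic (A), shared-environment (C) or dominance (D), and
non-shared (E) fractions. The expected cross-twin covariances are

* MZ: `a² + c²` (ACE) or `a² + d²` (ADE),
* DZ: `a²/2 + c²` (ACE) or `a²/2 + d²/4` (ADE),

because DZ twins share half the additive effects and a quarter of the
dominance deviations. `fitTwinModel()` maximizes the bivariate-normal
likelihood over *raw* variance components constrained to be
non-negative (L-BFGS-B with a Nelder-Mead polish; the lower bound sits
at 1e-8 so the pair covariance matrix stays positive definite at the
boundary), then standardizes to fractions. Pairs with one missing
member contribute their univariate marginal likelihood, so the fit is
full-information. Starting values come from the constrained Falconer
estimates, floored at 0.05 so no component starts on the boundary it
may end up on.

Standard errors are delta-method transforms of the inverse observed
Hessian of the deviance. At a zero boundary the Hessian is one-sided
and the SE is reported as computed but flagged (`boundary`); this
mirrors the common reporting style "0.00 (0.02)" rather than truncating
the SE.

Two bookkeeping conventions matter for comparability with published
fit tables:

* **Degrees of freedom** are `nObs − k`, with `nObs` the number of
  observed phenotype values (both members of complete pairs plus
  singletons) and `k` the free parameters (mean plus variance
  components). Published tables sometimes use a different singleton
  accounting that cannot be reconstructed from the table alone; the raw
  counts (`nPairs`, `nLL`, `nObs`) are therefore carried on the fit
  object.
* **AIC** is reported as `−2LL − 2·df` (`aicDeviance()`), the
  convention under which dropping one parameter at equal deviance
  lowers AIC by 2 — the convention that reproduces the published fit
  tables cell-for-cell. The textbook `−2LL + 2k` is available as
  `aicTextbook`.

`falconerEstimate()` implements the closed-form arithmetic
`a² = 2(rMZ − rDZ)`, `c² = 2rDZ − rMZ`, `e² = 1 − rMZ`. With
`constrain = TRUE` it encodes two facts: a variance fraction cannot be
negative, and heritability cannot exceed the MZ correlation. The cap
binds exactly when `rDZ < rMZ/2` (the non-additive signature), in which
case `c²` is zero and `a² = rMZ`.

`twinDataFromSummary()` manufactures complete pairs whose *sample*
moments equal the supplied correlations exactly (empirical whitening
followed by recoloring). Because the bivariate-normal likelihood
depends on the data only through these moments, fitting to such data is
a deterministic way to fit published summary statistics; the intraclass
correlation uses n-divisor mean squares precisely so that it agrees
with the Pearson correlation of double-entered data and hence with the
enforced moments.

## SNP heritability by GREML

`computeGRM()` implements the allele-frequency-standardized relatedness
estimator with the bias-adjusted diagonal. Frequencies are estimated
from the analyzed sample, which has one structural consequence worth
knowing: centered genotype scores sum to zero across the sample, so
off-diagonals average exactly `−mean(diag)/(n−1)` rather than zero.
Tests of "unrelatedness" are made relative to that center. Missing
dosages are handled pairwise-complete, with per-pair SNP counts kept on
the object. `pruneUnrelated()` applies the standard 0.025 cutoff
(fourth-degree relatives), iteratively removing the sample in the most
offending pairs, ties broken by lower call rate and then id order.

`remlH2()` fits `Var(y) = σ_g² A + σ_e² I` by restricted maximum
likelihood. Because the model has a single ratio parameter, the
restricted likelihood is profiled: project out the covariates with an
orthonormal basis, eigendecompose the projected GRM once, and the
profile over `h² ∈ [0, 1]` is a smooth one-dimensional function that
Brent search optimizes globally (total variance is profiled out
analytically). This avoids AI-REML iteration entirely and cannot
converge to a local mode. The SE comes from the numerical second
derivative of the profiled restricted log-likelihood; a GRM numerically
proportional to the identity makes the two components unidentifiable
and is rejected with an explicit error. The unconstrained search
(`bounded = FALSE`) is available for diagnostics.

Two properties shape expectations at realistic scale: the sampling
error of `h²_SNP` is roughly `sqrt(2m)/n` for an m-SNP GRM over n
unrelateds, so desk-scale designs (n in the low thousands) have SEs an
order of magnitude larger than twin-model SEs; and a phenotype's
composite across ages has *higher* SNP heritability than any single age
whenever the genetic effect is shared and residuals are imperfectly
correlated, so parameter-recovery checks in this package target a
single age, where the generator's `h2snp` is the exact truth.

## The longitudinal equal-effect score test

The association scan tests, per SNP, that the dosage has an equal
additive effect on the phenotype at every age — a single parameter,
hence 1 df. The test is a generalized-least-squares efficient score:

1. fit age-specific nuisance coefficients on covariates only (per-age
   OLS, then one GLS refit of the stacked model);
2. estimate the cross-age residual covariance Σ̂ from
   pairwise-complete residual products (age pairs never observed
   together get covariance 0; a non-positive-definite Σ̂ falls back to
   its diagonal with a warning);
3. with `W_i = Σ̂[s(i), s(i)]⁻¹` on individual i's observed ages,
   accumulate `U = Σ_i g_i 1'W_i r_i` and
   `V = Σ_i g_i² 1'W_i 1 − C'M⁻¹C`, where `C` and `M` are the
   score–nuisance cross-products; `U²/V` is referred to χ²₁.

Because the null model conditions on exactly the covariates that drive
missingness, outcomes missing at random given those covariates do not
bias the test — individuals simply contribute the ages they have, and
someone with no observed age drops out. When everyone has one age the
statistic collapses to the familiar univariate score test (the tests
verify this against an independently coded weighted-least-squares
oracle, and against the squared t statistic). The per-missingness
pattern bookkeeping makes the computation a handful of matrix products,
so a 20,000-SNP by 2,000-individual null scan runs in seconds.

Genomic control follows the median convention
`λ = median(stat)/0.4549364`, estimated separately per imputation
stratum; statistics are divided by `max(λ, 1)` — inflation is
corrected, deflation is left alone, which makes the adjustment
conservative. Significance tiers use strict inequalities at 5×10⁻⁸
(genome-wide) and 5×10⁻⁶ (suggestive). The risk allele is whichever
allele's dosage associates with a higher phenotype (the sign of `U`).

## Quality control

SNP filters run in a fixed order — info score, MAF, missingness,
Hardy-Weinberg, plate effect — and the first failing rule is the
recorded reason, so rule counts partition the exclusions. Boundary
semantics are strict (`info < 0.975`, `MAF < 0.01`,
`missingness > 0.02`, `HWE p < 1e-20`, `plate p < 1e-6`). Imputed SNPs
pass instead through a tiered info rule (≥ 0.90 when typed on a second
array, ≥ 0.98 when imputed throughout). Design notes:

* the info score is carried as SNP metadata: it is a property of the
  upstream calling/imputation step, which this package does not
  perform; only the threshold logic is implemented here;
* the HWE test uses rounded dosages and a Pearson 1-df chi-square; at a
  1e-20 threshold the asymptotic and exact tests agree to the order of
  magnitude that matters, and the exact conditional test is available
  behind `exact = TRUE`;
* the plate-effect test is a one-way ANOVA F of dosage on plate label —
  the simplest association between a quantitative dosage and a batch
  factor;
* sample call-rate (0.97) and heterozygosity (±3 SD) cutoffs are
  package defaults, configurable and logged, since no canonical values
  exist; relatedness removal drops the lower-call-rate member of each
  offending pair iteratively, which terminates because every step
  strictly reduces the number of offending pairs.

LD pruning is the greedy left-to-right scan within a window measured in
retained SNPs (`r² > 0.2` drops the later SNP); PCA standardizes
dosages by `(x − 2p̂)/sqrt(2p̂(1−p̂))` after mean imputation; and the
number of ancestry components is chosen by the sequential Tracy-Widom
test with tabulated critical values (0.9793 at α = 0.05) and the
effective-marker correction, stopping at the first non-significant
eigenvalue.

## Power

`qtlPower()` is the exact noncentral chi-square 1-df tail at the
central quantile for the chosen α. Two noncentrality conventions are
exposed — `n q²/(1 − q²)` (the regression likelihood-ratio
noncentrality, the default) and `n q²` — because published power
figures computed with external calculators rarely state which was used;
at desk-relevant effect sizes the two differ by well under two
percentage points. `qtlPowerSim()` is a simulation cross-check with a
binomial QTL and Monte-Carlo standard error.

## What the generator emulates, and what it does not

`simulateTwins()` draws from the Gaussian liability model with exact
factor-sharing coefficients (A shared 1/0.5 for MZ/DZ, D 1/0.25, C
1/1), which is precisely the covariance algebra the twin likelihood
assumes — so parameter recovery exercises the fitter, not the realism
of the model. `simulateGenotypes()` draws SNPs independently (no LD)
in HWE within subpopulations, with Balding-Nichols frequency
divergence when stratification is requested; `fst` and the
subpopulation count are free parameters because their only role here is
to exercise the PCA/Tracy-Widom machinery.
`simulateLongitudinalPhenotypes()` gives every age the same polygenic
score (rescaled to make `h2snp` the exact sample variance share, so a
single simulation is informative), exchangeable-correlation residuals,
additive sex/cohort effects, and logistic missingness driven by sex and
cohort only — missing at random by construction. The cross-age residual
correlation of the real trait is not published, so it is an explicit
parameter (`crossAgeCorr`, default 0.5) rather than a baked-in value.

None of this reproduces real arrays: there is no LD structure, no
imputation uncertainty beyond an assigned info score, no rater or
batch artifacts beyond the plate label. Passing tests therefore show
that the estimators recover the truth under their own assumptions at
the stated sample sizes — they do not validate the assumptions against
real data, and quantities that depend on real array content (such as
the fraction of SNPs a QC pass removes) are not reproduction targets.

The pipeline normalizes each age separately (van der Waerden,
`Φ⁻¹(r/(n+1))` with average ranks for ties — the symmetric choice that
keeps tie-free output mean-zero) before the association scan, and
residualizes the composite on covariates before the twin and GREML
stages; both orderings are configurable, since published descriptions
rarely pin down which normalization preceded which analysis.

## Problem sizes and determinism

The test suite runs its calibration experiments at sizes chosen to make
sampling noise small relative to the tolerances while keeping a default
run fast: twin recovery at the study's own 1099/1787 pair counts, GREML
recovery at n = 2000 with a 5000-SNP GRM (SE ≈ 0.05), the null scan of
the longitudinal test at 20,000 SNPs by 2,000 individuals, and smaller
grids elsewhere. Every generator call takes an explicit integer seed,
and all results are bit-reproducible given the seed; the pipeline
writes its seed and every threshold into the run manifest.

## Known limitations

Single genetic variance component only (no GxE, no multiple GRMs); no
multivariate twin decomposition, sex-limitation or rater-bias models;
no mixed-model association (the GRM is not used to adjust the scan);
LD-free simulation only; and the equal-effect score test assumes the
common-effect alternative — a SNP whose effect changes sign across
ages can be invisible to it, which is a property of the design, not a
bug of the implementation.
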