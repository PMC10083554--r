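---
title: "Methods: distributed case-control analysis of structural brain asymmetry"
author: "asymmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distributed case-control analysis of structural brain asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymmeta)
```

## The problem and the model

Case-control differences in structural brain asymmetry are small (Cohen's
*d* below 0.1 in recent consortium work), so credible estimation requires
thousands of individuals scanned at many sites, under data-sharing rules
that usually forbid pooling raw data centrally. `asymmeta` implements the
two-arm design used for this situation:

1. a **distributed univariate arm**, in which each site fits linear models
   on its own data and shares only summary statistics, which the central
   team pools by random-effects meta-analysis; and
2. a **pooled multivariate arm** for the subset of datasets whose
   individual-level data can be centralised, in which all regional
   asymmetries are tested jointly after batch harmonization.

### Asymmetry index

For each bilaterally paired measure with left and right values $L$ and $R$,

$$\mathrm{AI} = \frac{L - R}{(L + R)/2}.$$

The denominator removes the automatic scaling of $L - R$ with the size of
the structure, making indices comparable across regions; for positive
measures the index is bounded in $(-2, 2)$, positive when the left side is
larger. Measures are 34 Desikan-Killiany cortical regions (thickness and
surface area), one hemisphere-level average per cortical modality, and 8
subcortical volumes: 78 indices in three testing families (35 thickness,
35 area, 8 subcortical).

Two data-hygiene rules precede the index: raw values equal to zero are set
missing (they indicate data-entry errors, not anatomy), and a missing
value on either side blanks the other side, so an index is never formed
from a half-complete pair. Negative raw values are rejected with an error
rather than silently blanked: thickness, area and volume cannot be
negative, so a negative value indicates corrupted input that should stop
the pipeline. Both rules live in `clean_pair()`; `build_ai_table()`
applies them before computing any index.

As an advisory check on left/right image orientation,
`flag_orientation()` compares each dataset's mean index for a strongly
lateralised reference measure against the cohort consensus and warns on a
sign reversal. This is a deliberately conservative stand-in for
image-level orientation QC, which cannot be reproduced from derived
measures alone; it never flips or alters data.

### Per-site models and effect-size conversion

Within each dataset, each index is regressed on diagnosis (control = 0,
case = 1) with sex and age as covariates (`m1`), adding $n-1$ scanner
dummies in multi-scanner datasets (reference level: lexicographically
first scanner id). Sensitivity variants add handedness, intracranial
volume, both, or a centred squared-age term (`m2_hand` ... `m5_age2`);
interaction models add diagnosis-by-age or diagnosis-by-sex products and
extract the interaction term (`m8_dx_by_age`, `m9_dx_by_sex`); the
medication model (`m6_medication`) is fitted among cases only and
extracts the first- versus second-generation antipsychotic contrast.

A dataset is skipped for a model when its analysed sample is smaller than
$10 + \#\text{scanner dummies}$ or when either group has fewer than five
members; skipping is recorded, not an error. Collinearity is screened per
dataset with variance inflation factors ($1/(1-R^2)$ of each predictor on
the others); VIF > 5 flags the result but never drops a predictor.

The diagnosis (or interaction) $t$ statistic is converted to Cohen's *d*:

$$d = \frac{t\,(n_1 + n_2)}{\sqrt{n_1 n_2}\,\sqrt{\mathrm{df}}},\qquad
\mathrm{se}(d) = \sqrt{\frac{n_1+n_2-1}{n_1+n_2-3}\cdot\frac{4}{n_1+n_2}
\left(1 + \frac{d^2}{8}\right)},$$

with the 95% CI $d \pm 1.96\,\mathrm{se}(d)$. Note that for the
covariate-free two-group model this conversion equals the classical
pooled-SD Cohen's *d* times $\sqrt{N/(N-2)}$ exactly — a finite-sample
factor of the stated formula, negligible at the sample sizes involved but
asserted exactly in the test suite.

### Random-effects pooling

Per-dataset effects are pooled under $d_i \sim N(\mu, se_i^2 + \tau^2)$
with $\tau^2$ estimated by restricted maximum likelihood. The solver is
Fisher scoring on $\tau^2$ (score over expected information), floored at
zero, with three safeguards chosen for unattended batch use: steps are
halved until the restricted likelihood does not decrease, the boundary
$\tau^2 = 0$ is always compared as a candidate (the profile likelihood can
be maximised at the boundary, where plain scoring may stall), and
non-convergence after 100 iterations falls back to the DerSimonian-Laird
estimate with a warning. Convergence tolerance is $10^{-8}$ on the
$\tau^2$ step. Inference is by the Wald $z = \hat\mu / \mathrm{se}(\hat\mu)$
with $p = 2\Phi(-|z|)$ (no Knapp-Hartung adjustment, matching the
reported z statistics); Cochran's $Q$ and $I^2$ are reported at
fixed-effect weights. The test suite verifies $\hat\tau^2$ against an
independent grid search of the restricted likelihood and against
`metafor::rma` at a tightened convergence threshold.

False-discovery control uses Benjamini-Hochberg within each measure family
(35/35/8 for the primary analysis; all tested indices form one family in
the interaction, medication and clinical scans), significance at
$q < 0.05$.

Sensitivity machinery: `meta_regress()` fits a single dataset-level
moderator with REML $\tau^2$ and a Wald omnibus chi-square on its
coefficients; `outlier_sensitivity()` flags datasets whose externally
studentized deleted residual exceeds 2.5 in absolute value and re-pools
without them, reporting both results. The 2.5 threshold is a configurable
declared default — the outlier rule is a design choice of this package,
not a published constant. Within-case clinical correlations are computed
per dataset as partial correlations adjusting age and sex (a declared
interpretation; the estimator is configurable in principle because pooled
correlations are reported without their construction in the literature)
and pooled on the Fisher-z scale with the same REML machinery, using
$se = 1/\sqrt{n - 3 - k}$ with $k$ the number of partialled covariates.

### The pooled multivariate arm

Datasets whose individual-level data are available are pooled, restricted
to individuals with complete data on all 76 regional measures, and the
left- and right-hemisphere matrices are harmonized **separately** with
ComBat (parametric empirical-Bayes location/scale adjustment), batch =
dataset-by-scanner, preserving diagnosis, age and sex. Asymmetry indices
are recomputed from the harmonized hemispheres — never harmonized
directly — because harmonizing a ratio of adjusted quantities is what the
index definition requires. Individuals left with a non-positive adjusted
volume are dropped (the adjustment can push extreme small volumes below
zero, where the index is undefined); a correlation screen warns if any
pairwise $|r|$ between indices exceeds 0.5.

The joint test is a MANCOVA of all 76 indices on diagnosis with age and
sex covariates: Wilks' $\Lambda = \det(E)/\det(E+H)$, converted by Rao's
approximation, which is exact in form for this single-df hypothesis:
$F = \frac{1-\Lambda}{\Lambda}\cdot\frac{\mathrm{df}_2}{\mathrm{df}_1}$,
$\mathrm{df}_1 = p = 76$, $\mathrm{df}_2 = N - \mathrm{rank}(X) - p + 1$.
The share of multivariate variance associated with diagnosis is
$1 - \Lambda$. Because $H$ has rank one, $\Lambda$ is computed by the
rank-one identity $\Lambda = 1 - h^\top T^{-1} h / s$ (with $Y$ and the
diagnosis vector residualised against the covariates, $T = Y_r^\top Y_r$,
$h = Y_r^\top d_r$, $s = d_r^\top d_r$), which the tests verify against
`stats::manova` and against the eigenvalue identity
$\Lambda = 1/(1+\lambda_1)$.

Significance is assessed by label-swapping permutations **stratified by
dataset-by-scanner**: each draw permutes diagnosis labels only within a
stratum, preserving every stratum's case/control counts, so site and
scanner structure is held fixed under the null. The permutation p-value is
the count of permuted $F \ge$ observed $F$ divided by the number of
permutations — deliberately *not* the $(b+1)/(B+1)$ form, for fidelity to
the stated estimator; a zero count therefore reports $p = 0$ and the
result carries the resolution $1/B$ alongside. Each permutation's RNG
stream is derived from (seed, permutation index), so the p-value is
identical for any chunking or execution order. The default is
$B = 10{,}000$ for desk-scale runs; $10^6$ is a configuration value.
Univariate ANCOVA follow-ups per index (same individuals, same
covariates) are reported as a nominally-ranked table without FDR, as a
reading aid for the joint test.

## The synthetic cohort generator

Every stage is exercised end-to-end on `generate_cohort()`, which draws,
for each individual and region, a latent bilateral size
$M \sim N(\text{baseline mean} \times \text{site scale},\;
\text{baseline SD} \times \text{noise inflation})$ truncated positive, and
a latent asymmetry

$$A = \text{baseline AI} + \text{site shift} + \beta_{\text{age}}\,
\mathrm{age}_c + \beta_{\text{sex}}\,\mathrm{sex} +
\mathrm{dx}\,(d_{\text{true}}\,\sigma_{AI}) + \dots + \varepsilon,$$

then sets $L = M(1 + A/2)$ and $R = M(1 - A/2)$, so the index formula
recovers $A$ exactly — an analytic oracle for every downstream stage.
Effects specified on the Cohen's-d scale are converted to index units
through $\sigma_{AI}$, the region's simulated index SD *at that site*
(baseline index SD times the site's noise inflation), which makes
$d_{\text{true}}$ recoverable as a *d* at every site regardless of its
noise level. Age terms are centred at 33 years. Missing values and exact
zeros are injected cell-wise after construction.

Defaults, chosen once as the study conditions for all tests:

* **Layouts**: 14 sites averaging ~145 individuals (the scale of a pooled
  individual-level subsample, ~2,000 individuals) as the default;
  45 sites averaging ~244 (~11,000 individuals, ~46% cases) as the
  consortium scale. Sites vary deterministically in size, age structure
  (means 25-41 y), sex composition (67% male cases, 52% male controls),
  scanner count (every fifth site has two scanners), multiplicative
  measurement scale (±6%), additive index offsets (±0.008) and noise
  inflation (1-1.3). An optional case-only site mirrors consortia that
  contribute one; case-control stages must skip it.
* **Artifact rates**: 0.001 missing and 0.0005 exact-zero per left/right
  cell. Over 152 cells per individual this retains ~80% of individuals
  under the complete-data rule of the multivariate arm, matching the
  retention proportions typical of consortium tables; the rates are
  configurable per `effect_spec()`.
* **Covariate effects**: a small default age slope on all indices
  (-2e-4/year) and sex effect (+0.005), so covariate adjustment is doing
  real work; `null_effect_spec()` switches everything off for calibration
  studies.
* **Baselines**: plausible adult FreeSurfer-scale means and SDs per
  region; mean indices small (|AI| <= 0.05 thickness, <= 0.1 area and
  volume) — region-level asymmetry magnitudes are not published as a
  numeric table, so these are order-of-magnitude defaults, configurable
  through the catalog.

What the generator deliberately does **not** emulate: segmentation
failures that are correlated within a scan session, non-Gaussian site
effects, scanner upgrades over time within a dataset, diagnosis-dependent
missingness, and any image-level artefact. Passing tests therefore
demonstrate that the statistical machinery recovers known truth under the
stated noise model — not that the pipeline is robust to every real-world
failure mode of multi-site MRI.

## Validation design and problem sizes

The test suite ties each estimator to an independent oracle: REML
$\hat\tau^2$ to a restricted-likelihood grid search (100 random 10-study
sets); BH q-values to the brute-force step-up definition (1,000 random
vectors); the d conversion to classical two-group Cohen's d through its
exact finite-sample factor; Wilks' F at $p=1$ to `summary.aov`; the full
MANCOVA to `stats::manova`. Calibration of the stratified permutation
test uses 200 global-null cohorts (14 sites, ~2,000 individuals, 1,000
permutations each), asserting the rejection rate at $\alpha = 0.05$
within binomial 99% bounds and uniformity of the permutation p by a
Kolmogorov-Smirnov check. Parameter recovery uses 20 consortium-scale
cohorts (45 sites, ~11,000 individuals) with $d_{\text{true}} = -0.08$ on
two cortical thickness indices, asserting >= 90% CI coverage of the truth
and that the seeded regions take the two smallest within-family q-values
in a majority of replicates. These sizes were chosen as the smallest that
make the assertions statistically meaningful.

## Known limitations

* **ComBat re-application is not a fixed point.** Empirical-Bayes
  shrinkage removes the *shrunk* batch estimates, leaving a small residual
  that a second pass partially re-estimates; the observed relative RMS
  change on re-application is of order $10^{-3}$, not machine precision.
  This is a property of the EB location/scale model itself, not of the
  implementation; exact idempotence would require disabling shrinkage.
  The acceptance suite documents this gap with a failing assertion at the
  idealised $10^{-6}$ bound.
* The permutation p-value convention (count over count, without the +1
  correction) can report exactly zero; consumers should read it together
  with the reported resolution $1/B$.
* Harmonization requires at least two individuals per batch and complete
  data; singleton batches are rejected rather than silently merged.
* The orientation flag is a heuristic on derived indices; it cannot
  detect a flip that affects an entire cohort uniformly.
* Medication contrasts and clinical correlations inherit the reduced
  sample sizes of their variables; the package reports per-scan `k` so
  users can judge the effective evidence base.
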