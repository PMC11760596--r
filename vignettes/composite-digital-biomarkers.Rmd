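---
title: "Constructing composite digital biomarkers of disease progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing composite digital biomarkers of disease progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digicomp)
```

## The modelling problem

Wearable inertial sensors worn during standardized clinic tasks (a
two-minute walk, postural sway, timed up-and-go) yield hundreds of
kinematic features per subject per visit. In a longitudinal observational
study of Parkinson's disease with repeated visits, the scientific goal is
a single *composite digital measure* that (i) tracks disease progression
more sensitively and less noisily than the clinician-rated anchor score
it is trained against, and (ii) still separates newly diagnosed patients
from healthy controls. The statistical obstacles are the panel's high
dimensionality relative to the number of subjects, strong and unknown
correlation among features, within-subject correlation across visits,
skewness, missingness, and occasional sensor glitches.

`digicomp` addresses these with a fixed pipeline: quality control →
univariate mixed-model screening → (optional) univariate association
filtering → penalized-GEE multivariate selection → composite GEE →
evaluation. This vignette records the models, the tunable parameters and
their defaults, the numerical choices, and the design decisions taken
where the methodology leaves the choice open.

## The synthetic cohort generator

No suitable public dataset exists for this design, so the package treats
the simulator as a first-class module; every downstream stage is tested
against cohorts whose ground truth is known.

`cohort_config()` describes a study of four groups — de novo PD,
mild-to-moderate PD on therapy, advanced PD, and healthy controls (HC) —
with `n_per_group = 10` subjects each and visits at 0, 3, ..., 24 months.
Feature `k` of subject `j` in group `g` follows

  y_jk(t) = mu_gk + b0_jk + (s_gk + b1_jk) t + e_jk(t),

with per-subject-per-feature random intercepts `b0 ~ N(0, 1)` and slopes
`b1 ~ N(0, 0.02^2)` and residual SD 1. Defaults give the first five
features ("progressive") slope 0.15/month in de novo PD and 0.10/month in
advanced PD, zero in treated PD and HC — the qualitative pattern the
framework is meant to detect (the treated group is stabilized by
medication) — plus a baseline group separation (1.0 / 1.5 / 2.5 / 0 on
the progressive features) so that classification is informative.

Residual correlation within blocks of `corr_block_size = 5` consecutive
features (pairwise `feature_corr = 0.3`) is induced by a shared Gaussian
latent factor per block and visit: the simplest controllable mechanism
for the "unknown redundancy" of real panels. Skew-listed features
(default: the last two) are exponentiated, i.e. generated on the log
scale. Cells go missing completely at random at rate 0.05; MCAR is the
only mechanism under which the pipeline's mean imputation is defensible,
and the generator deliberately matches that assumption. Outliers
(rate 0.002) shift a value by 5 residual SDs — large enough to be flagged
by the per-value outlier rule, small enough that a feature is not
wholesale removed by the extreme-value filter.

The clinical anchor is a weighted sum of the *noise-free* latent feature
signals plus `N(0, 5^2)` noise and an offset of 20, placing it in a
0–80-like range. It is continuous by default (`anchor_round = FALSE`):
although real motor scores are integer-valued, the framework models them
as continuous, and rounding is available as a flag. What the generator
does *not* emulate: biomechanical structure of real gait signals,
floor/ceiling effects, informative missingness, or visit-time jitter —
so passing tests demonstrate statistical correctness of the pipeline, not
clinical validity on real data.

Age is drawn per group from Normal distributions matching the intended
design's demographics (means 66.2 / 61.6 / 71.2 / 65.6, SDs 6.46 / 10.76
/ 4.78 / 6.98); sex is Bernoulli with male proportions 0.5 / 0.9 / 0.5 /
0.3. Neither influences the features by default; they exist so that
covariate selection runs against a realistic null.

## Quality control

`run_qc()` applies, in fixed order: non-informative filtering → mean
imputation → correlation pruning → log transform of skewed features →
per-value outlier removal → re-imputation. The thresholds live in
`qc_config()` and are package decisions (the methodology names the steps
but no numbers): at least 5 distinct observed values, at most 50% missing
cells, no robust z-score (median/MAD scaling) beyond 6 in magnitude,
correlation pruning at |r| > 0.95, log transform beyond absolute sample
skewness 2 (adjusted Fisher–Pearson form), and per-value removal beyond
robust z 4.

Three deliberate choices: correlation pruning iterates in descending
variance order (ties by name) and keeps the earlier member, making the
result deterministic and biased toward the more informative column;
outlier handling removes individual values and re-imputes rather than
dropping rows, preserving the longitudinal grid; and a feature whose MAD
is zero but which still has many distinct values is treated as containing
extreme values (any off-median value has infinite robust z). Note the
interplay between the extreme-value filter and the log transform: a
feature skewed enough to need the transform often contains values beyond
robust z 6 and is removed first. This mirrors the order the methodology
prescribes; panels where such features must survive should raise
`extreme_value_rule`.

## Univariate screening and association

Each feature is screened with the REML linear mixed model

  feature ~ covariates + group + visit + group:visit + covariate:visit
            + (visit | subject),

HC as reference, visit as continuous time in months (the framework
reasons about slopes throughout). Numeric covariates are centered so the
`visit` main effect is the HC slope at average covariate values. The
omnibus group-by-visit p-value is a multi-degree-of-freedom Wald
chi-square over the three interaction coefficients — the only sensible
reading of a single "interaction p-value" for a four-level factor. All
coefficient tests are Wald normal approximations: fast, standard, and
adequate at these sample sizes, at the cost of mild anti-conservatism in
small samples (the acceptance battery quantifies this). If the
unstructured random intercept+slope fit fails or is singular, the model
falls back to uncorrelated effects, then to a random intercept only, and
a feature that still fails is excluded with a logged reason.

A feature passes screening when its HC trend is flat (p > 0.05) *and* it
progresses in PD (omnibus p < 0.1 or some PD-vs-HC differential slope
p < 0.1). These relaxed thresholds are intentional — screening feeds a
penalized selector, so false positives are cheap and false negatives are
not — and no multiplicity correction is applied, consistent with that
role. Worth knowing: with four chances at these levels, the expected null
pass rate is ≈ 0.2, so a screened panel always carries noise features
into selection. The differential-slope p-values are contrasts of the full
interaction model, not separate two-group refits — the stricter and more
efficient reading.

`association_test()` relates the clinical score to each candidate with a
random-intercept LMM; `select_covariates()` picks adjustment covariates
whose covariate-by-visit interaction is significant at 0.05 in the pooled
PD subset.

## GEE and SCAD-penalized GEE

The package implements classical GEE from scratch: Fisher scoring on
`sum_i D_i' V_i^{-1} (y_i - mu_i) = 0` with moment re-estimation of the
working correlation each iteration (exchangeable: pairwise cross-products
over dispersion; AR(1): lag-1 products; both clipped to (−0.99, 0.99) and
exchangeable additionally kept above −1/(max cluster size − 1) for
positive definiteness), model-based and sandwich covariances, gaussian
and binomial-logit families. For the gaussian identity case with
independence or exchangeable correlation the inverse working correlation
has the closed form aI + bJ, and the solver uses a loop-free
accumulation; the generic per-cluster path covers binomial and AR(1), and
the two paths agree to 1e-10 (tested).

The penalized variant augments each step by a local quadratic
approximation of the SCAD penalty (shape a = 3.7, the conventional
choice), `beta <- beta + [H + nE]^{-1} [U - nE beta]` with
`E_jj = q_lambda(|beta_j|) / (1e-6 + |beta_j|)` on penalized columns.
Penalized columns are standardized internally and coefficients are
reported on the standardized scale — penalties and magnitude rankings are
meaningless across heterogeneous units otherwise — with raw-scale
coefficients also returned. Coefficients below `zero_cutoff = 1e-3`
(standardized) count as zero. The initializer is a small ridge solve:
starting from exact zero would trap every penalized coefficient at zero
under the quadratic approximation. Convergence is max |update| < 1e-6 or
200 iterations; a step that grows tenfold beyond the initial step aborts
with diagnostics.

### Choosing the penalty

`tune_lambda()` cross-validates over clusters (subjects), never rows.
Each candidate λ is scored by the *features it selects*, not by its
shrunken coefficients: the penalized fit on the training clusters fixes
the support, an unpenalized GEE is refit on that support, and the refit
predicts the held-out clusters. The reason is structural: SCAD estimates
are taper-biased precisely in the λ range that zeroes noise features
(|beta| < aλ), so scoring the shrunken fit rewards under-penalization and
reliably over-selects. Scoring the refit makes the loss a function of the
selected set alone — the same principle the feature-count CV below uses.
The default selection rule is the one-standard-error rule (largest λ
within one SE of the minimizer), the standard parsimony tie-break for
penalized CV; the strict minimizer is available via `rule = "min"`.
The default grid is 15 log-spaced points from the largest marginal score
down to 2% of it.

Working correlations default to exchangeable for the continuous
(progression) endpoint — repeated visits share subject effects — and
independence for the binary de novo PD vs HC endpoint, whose clusters are
small. Both are configurable.

### Choosing the number of features

`choose_feature_count()` ranks features per training fold by
standardized PGEE estimate magnitude (zeros excluded, ties by name), then
for each k refits an *unpenalized* GEE on the top-k features plus
covariates and scores held-out subjects: RMSE for progression, AUC for
classification. Folds are subject-level and group-stratified (default
10), so no subject is ever on both sides. The chosen P is the argmin
(RMSE) or argmax (AUC) of the mean curve, ties toward smaller k. One
numerical subtlety: because each fold can only rank as many features as
its penalized fit selects, the mean curve is compared only across k
values scored in *every* contributing fold — averaging a large k over
the lone folds that happened to rank that many features would let a
single easy fold masquerade as a better feature count. λ is
tuned once on the full candidate set and shared across folds — a
documented simplification that avoids nested tuning. Ranking is per fold,
the stricter reading of "ranked on the training set".

## The composite measure and its evaluation

`fit_composite()` regresses the clinical score on the merged,
standardized final feature set plus covariates with a gaussian
exchangeable GEE; the stored standardization makes the model a function
from a subject-visit row to a score. Covariate terms are included in the
score by default (the model is trained with them); a covariate-free
scoring mode is a flag on `score_composite()`.

Evaluation deliberately separates concerns:

* **Progression** — the screening LMM refit with the composite as
  response; reported: omnibus group-by-visit p, HC slope p, per-PD-group
  differential slope p.
* **Effect sizes** — Cohen's d on per-subject OLS slopes of the score
  over time, pooled-SD denominator, 95% CI as d ± 1.96·SE(d) with the
  standard large-sample SE. This definition is stated prominently because
  effect sizes on slopes are not uniquely defined and numbers depend on
  it.
* **Variability** — between/within-subject coefficients of variation from
  a one-way random-effects (ANOVA method-of-moments) decomposition of the
  score by subject, each component's square root divided by the grand
  mean. The grand mean must be positive; scores are never re-centered
  silently.
* **Classification** — Mann–Whitney AUC over pooled subject-visit scores
  of the de novo PD and HC groups, threshold maximizing the Youden index
  (ties toward the lower threshold), confusion counts at that threshold.
* **Cross-validated RMSE** — per group, from subject-level 10-fold CV in
  which each subject is scored by a model trained without them.

## Problem sizes used in the test suite

The automated tests run the pipeline at deliberately modest sizes chosen
to exercise every code path with stable statistics: support-recovery
simulations use 100 clusters of 4 visits with 50 penalized features (50
replicates), screening operating characteristics use a 200-feature panel
at 20 subjects per group, the feature-count CV uses 25 replicates of a
20-feature panel with 3 informative features, and the end-to-end pattern
check uses 25 replicates at 20 subjects per group. Calibration bands in
the tests are wide by design: small-sample Wald tests are approximate,
and the screening rule's union of correlated tests has a null pass rate
near 0.2 by construction.

## Known limitations

* Wald normal p-values are mildly anti-conservative for small cohorts;
  Satterthwaite-type corrections are not implemented.
* Mean imputation is only defensible under MCAR; the package neither
  detects nor models informative missingness.
* The PGEE solver offers SCAD only; no post-selection inference is
  provided, and selected-feature p-values should not be read as honest.
* The composite is linear in (possibly log-transformed) features by
  construction; saturating or threshold effects of real sensor features
  are outside the model family.
* The synthetic generator's Gaussian-on-(log-)scale marginals are an
  assumption of convenience; the distributional family of real digital
  features is not modelled.
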