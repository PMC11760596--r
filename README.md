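# digicomp

Composite digital biomarkers of disease progression from longitudinal,
high-dimensional wearable-sensor feature panels.

## The problem

Clinical rating scales for neurodegenerative diseases (the motor
examination MDS-UPDRS Part III for Parkinson's disease being the
canonical example) are subjective, noisy, and slow to change, which makes
disease-modifying trials large and long. Body-worn sensors produce
hundreds of objective movement features per clinic visit — gait speed,
turn velocity, sway area, and so on — but no single feature outperforms
the clinical composite, and the panels are high-dimensional, mutually
correlated, skewed, and incomplete. `digicomp` implements an end-to-end
statistical pipeline that turns such a panel into a single *composite
digital measure* anchored to the clinical score:

1. **Aggregation & QC** — epoch-level measurements (per step, per turn)
   are collapsed into task-level summary statistics (mean, median, SD,
   mean absolute deviation), then filtered for non-informative columns,
   mean-imputed, pruned of high correlations (|r| > 0.95), log-transformed
   where skewed, and cleaned of per-value outliers.
2. **Univariate progression screening** — per feature, a linear
   mixed-effects model `feature ~ covariates + group + visit +
   group:visit + covariate:visit + (visit | subject)` is fit with healthy
   controls (HC) as reference. A feature passes when its HC trend is flat
   (slope p > 0.05) and it progresses in the disease groups
   (group-by-visit p < 0.1 or some PD-vs-HC differential slope p < 0.1).
3. **Univariate association** — each candidate is related to the clinical
   score through a random-intercept LMM (an optional filter).
4. **Penalized-GEE selection** — a generalized estimating equation with a
   SCAD penalty on the feature coefficients,

   solving `sum_i D_i' V_i^{-1} (y_i - mu_i) - n q_lambda(|beta|) sign(beta) = 0`

   by local quadratic approximation, performs simultaneous estimation and
   variable selection under a working within-subject correlation. The
   penalty level is chosen by cluster-level cross-validation, the number
   of top-ranked features P by subject-level cross-validation (RMSE for
   the continuous endpoint, AUC for de novo PD vs HC classification), and
   the progression and classification feature sets are merged.
5. **Composite & evaluation** — a gaussian GEE of the clinical score on
   the merged, standardized feature set plus covariates defines the
   composite measure, which is evaluated by cross-validated RMSE,
   progression p-values and effect sizes per disease group, between- and
   within-subject coefficients of variation, and de novo PD vs HC
   classification (Mann-Whitney AUC, Youden threshold).

Because real cohorts of this design are rarely shareable, the package
ships a synthetic cohort generator (`generate_cohort()`) reproducing the
study structure: four groups (de novo PD, mild-to-moderate PD on therapy,
advanced PD, HC) of 10 subjects seen every 3 months for 2 years, with
group-specific feature slopes, random intercepts/slopes, block-correlated
residuals, skewness, missingness, outliers, and an anchor score driven by
the latent progression.

## A worked example

```r
library(digicomp)

cohort <- generate_cohort(cohort_config(seed = 11))   # 40 subjects x 9 visits
qc     <- run_qc(cohort)                              # 20 -> 18 features kept
scr    <- screen_panel(qc$data)                       # univariate screening
cand   <- scr$feature[scr$pass]                       # 9 candidates pass

pick <- function(endpoint) {                          # P by subject-level CV,
  cv  <- choose_feature_count(qc$data, cand, endpoint, seed = 3)
  fit <- pgee_select(qc$data, cand, endpoint, lambda = cv$lambda)
  rank_features(fit)$feature[seq_len(cv$chosen_p)]    # top-P by |PGEE estimate|
}
final  <- merge_feature_sets(pick("progression"), pick("classification"))
scored <- crossvalidated_scores(qc$data, final, "age", n_folds = 10, seed = 5)
evaluate_composite(scored)
```

```
Composite digital measure evaluation
  group-by-visit p = 8.34e-31; HC slope p = 0.0865
  de_novo_pd vs HC: slope p = 1.68e-22, effect size 4.45 (2.75, 6.15)
  mild_moderate_pd vs HC: slope p = 0.622, effect size -0.21 (-1.09, 0.67)
  advanced_pd vs HC: slope p = 4.59e-09, effect size 2.48 (1.29, 3.67)
  CoV between/within = 0.184 / 0.132
  CV RMSE by group: de_novo_pd = 5.50, mild_moderate_pd = 5.62, advanced_pd = 6.24, hc = 6.17
  AUC (de novo PD vs HC) = 0.932 at threshold 27.867 (22 misclassified)
```

Read: the composite (built on the merged 4-feature set
`feat04, feat02, feat03, feat01`) progresses strongly in the de novo and
advanced PD groups (tiny differential-slope p-values, large standardized
effect sizes), stays flat in HC (p = 0.087) and in the treated
mild-to-moderate group — matching the generator's truth — and separates
de novo PD from HC with AUC 0.932 at the Youden-optimal threshold.

The staged pipeline with on-disk artifacts (CSV/JSON plus a manifest per
stage) is available as `run_stage("all", pipeline_config(...))` or from
the shell via `inst/cli/digicomp.R`.

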