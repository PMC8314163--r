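# depsense

Digital biomarkers of depression from smartphone event logs: a complete,
synthetically testable analysis pipeline in R.

## The problem

Depression screening relies on sparse self-reports such as the 8-item
Patient Health Questionnaire (PHQ-8; total 0–24, with totals ≥ 10
labeled depressed). Smartphones passively observe behavior — screen
lock/unlock, internet connectivity, foreground app launches — sampled in
many sensing studies at each 1% battery change. `depsense` is for
researchers in digital phenotyping and mobile mental health who want a
tested, reproducible implementation of the full path from raw event logs
to depression-screening statistics and classifiers, together with a
generator of realistic synthetic cohorts on which every stage can be
validated.

The pipeline:

1. **Synthetic cohort** (`synth_config()`, `simulate_study()`):
   participants with demographic marginals and timezones, 8–86 days of
   battery-sampled event logs with controllable missing log intervals,
   PHQ-8 responses every 2 weeks from a latent AR(1) severity process
   with participant intercepts, and configurable depressed-state effects
   (a standardized shift in screen-state entropy, calibrated in closed
   form to a target correlation, plus an optional non-monotone
   internet-regularity perturbation).
2. **Preprocessing** (`localize_and_segment()`, `filter_days()`,
   `filter_responses()`): UTC → participant-local time, day
   segmentation, exclusion of days with ≥ 10 missing log intervals and
   of responses with < 8 retained days in their 14-day window.
3. **Features** (`extract_features()`): the 22 day-level markers —
   counts; Shannon entropy `H = −Σ pᵢ ln pᵢ` and normalized entropy
   `H / ln N` of screen, internet and app states; hour-by-hour
   regularity indices `R(a,b) = (1/24) Σₜ x̃ₐ(t) x̃_b(t)` on values
   rescaled to [−0.5, 0.5], averaged over same-ISO-week day pairs;
   epoch-count SDs over the four 6-hour day epochs; first/last app-use
   minutes.
4. **Pooling** (`pool_windows()`): one analysis row per PHQ-8 response —
   means over the window's days, pooled SDs
   `√(Σ(nᵢ−1)sᵢ² / Σ(nᵢ−1))` for the SD features, labels at the
   clinical cut-off, exact-duplicate removal.
5. **Statistics** (`pearson_with_holm()`, `icc_components()`,
   `pmm_impute()`, `lmm_associations()`): Pearson screen with Holm
   step-down adjustment; ICC from a random-intercept model; 20-fold
   predictive-mean-matching imputation; per-feature bivariate linear
   mixed models `total ~ feature_z + (1 | participant)` pooled by
   Rubin's rules with Benjamini–Hochberg adjustment.
6. **Classification** (`nested_cv()`, `smote()`, `rwc_baseline()`,
   `dt_baseline()`, `permutation_importance()`): stratified nested
   10×3-fold cross-validation with grid search on macro-F1, SMOTE
   applied strictly inside training partitions, five classifiers
   (RF, RBF-SVM, XGBoost, KNN, logistic regression), random-weighted and
   demographic decision-tree baselines, and AUC-based permutation
   feature importance. `cv_config(group_folds = TRUE)` adds
   participant-grouped folds that remove repeated-measures leakage.

Results are tibbles throughout; fitted objects have broom-style
`tidy()`/`glance()` methods and ggplot2 `autoplot()`/`plot_importance()`
graphics. `run_pipeline()` executes everything end to end and writes
CSV tables, a JSON manifest and a plain-text report.

## Worked example

```r
library(depsense)

cfg    <- synth_config(n_participants = 60, seed = 42)
study  <- simulate_study(cfg)
study
#> <sensing_study>
#>   60 participants, 72788 event records, 1407 scheduled days, 98 PHQ-8 responses
#>   depressed responses: 14 (14.3%)

days      <- filter_days(localize_and_segment(study$events, study$profiles, study$schedule))
responses <- filter_responses(study$responses, days)
features  <- extract_features(days)
pooled    <- deduplicate_samples(pool_windows(features, responses))

assoc <- pearson_with_holm(pooled)
dplyr::arrange(tidy(assoc), p.adjusted)
#> # A tibble: 22 × 6
#>   term               estimate std.error   p.value p.adjusted method
#> 1 screen_offCount       0.421    0.0926 0.0000160   0.000325 pearson_holm
#> 2 screen_entropy        0.422    0.0925 0.0000148   0.000325 pearson_holm
#> 3 screen_normEntropy    0.422    0.0925 0.0000148   0.000325 pearson_holm
#> 4 screen_onCount        0.417    0.0928 0.0000199   0.000378 pearson_holm

icc_components(pooled$phq8_total, pooled$participant_id)
#> ICC = 0.8384 (between 14.5507, within 2.8036; reml estimator)

rwc_baseline(pooled$label, n_draws = 2000, seed = 1)
#> # A tibble: 6 × 4
#>   metric       mean     sd       se
#> 1 accuracy  0.756   0.0343 0.000766
#> 2 precision 0.146   0.0869 0.00194
#> 3 recall    0.146   0.0915 0.00205
#> 4 f1        0.144   0.0856 0.00191
#> 5 auc       0.502   0.0489 0.00109
#> 6 kappa     0.00357 0.0969 0.00217
```

Reading the output: this 60-participant cohort was generated with the
default depressed-window entropy shift, so the screen-state entropy
features (and the tightly coupled screen counts) surface at the top of
the Holm-adjusted correlation screen — at this small clustered sample
the estimate (r ≈ 0.42) is noisy, and `pearson_cluster_se()` gives the
honest participant-clustered uncertainty. The outcome ICC of 0.84 shows
most PHQ-8 variance lies between participants, which is why the mixed
model and the grouped cross-validation mode exist. The random weighted
baseline sits at chance: κ ≈ 0, AUC ≈ 0.50, and precision/recall near
the 14–17% prevalence.

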