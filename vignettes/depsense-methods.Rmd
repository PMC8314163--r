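---
title: "Methods: digital biomarkers of depression from smartphone event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital biomarkers of depression from smartphone event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Passively sensed smartphone behavior — when the screen is locked and
unlocked, when the device is online, which apps come to the foreground —
carries information about a person's routines, and disruptions of routine
are a clinical hallmark of depression. `depsense` implements a complete
analysis pipeline for this setting: time-stamped event logs sampled at
battery-change events, repeated 8-item Patient Health Questionnaire
(PHQ-8) self-reports every two weeks, day-level behavioral markers,
window-level pooling onto each assessment, association statistics, and an
imbalance-aware nested cross-validated classification harness.

Because raw sensing cohorts of this kind are rarely shareable, the
package is built around a first-class synthetic-data generator
(`synth_config()`, `simulate_study()`) whose statistical structure mirrors
the study design every downstream stage assumes. All tests and the
reproduction script run entirely on generated data.

# The generator

## Study design

Each participant gets a follow-up period of 8–86 consecutive local days;
lengths are negative-binomial (moment-matched to a mean of 22.1 and SD of
17.9 days, so roughly half the cohort contributes only 8–14 days, as is
typical of crowdsourced deployments). PHQ-8 responses occur every 14
days (one response at the final day for participants followed under two
weeks). Demographics are drawn from published cohort marginals
(`default_demographic_marginals()`), and each participant receives an
IANA timezone consistent with their country, so UTC-to-local conversion
is a real part of the pipeline.

## Depression outcome

Latent severity is a participant intercept plus an AR(1) process over
2-week windows, scaled so the marginal is standard normal and the
intercept share equals the configured intraclass correlation (default
0.7584, giving strongly clustered repeated measures). The latent value is
mapped through the quantile function of a fixed PHQ-8 total distribution
(`phq8_total_pmf()`): a negative binomial matched to mean 5.19 and SD
5.22, truncated to 0–24, with the tail mass rescaled so that
`P(total >= 10)` equals the configured prevalence (default 0.1681)
*exactly* in the population. Item scores are a uniform random composition
of the total with each item capped at 3. This construction guarantees the
score range, the class balance, and high within-participant correlation
by design rather than by tuning. The ICC of the *observed* totals is
attenuated relative to the latent value because the quantile transform is
nonlinear; the package therefore treats ICC as a parameter-recovery
quantity (see `icc_components()` tests) rather than a number to match.

## Behavioral streams

Three streams are generated per participant-day, each by the simplest
process that controls the features it must drive:

* **Screen** (drives duration entropy): an alternating on/off dwell
  sequence whose dwell totals are rescaled so the realized on-duration
  share equals an entropy-targeted value exactly. The target normalized
  entropy of a day is `base mean + participant effect + day noise`
  (defaults 0.55, SD 0.10 between participants, SD 0.12 across days),
  inverted to an on-share through the binary entropy function. Days
  inside depressed assessment windows are shifted upward by
  `entropy_effect` day-level SDs — depressed participants lock and unlock
  their phones more erratically.
* **Internet** (drives the hourly regularity index): a participant
  template — connected except during a nightly offline block — with
  per-day, per-hour flip noise (default rate 0.18). When
  `nonlinear_effect_flag` is on, each depressed window flips a coin
  between an extremely routine (0.02) and an extremely erratic (0.34)
  flip rate. The two modes average to the baseline rate, so the injected
  structure is non-monotone: it moves variance, not the mean, and leaves
  linear correlations with internet counts at zero. This mirrors the
  intended data-generating story in which only screen-state normalized
  entropy carries a linear signal while nonlinear learners can still
  exploit internet regularity.
* **Apps** (no injected signal): a Poisson launch process (gamma
  participant rates, mean 30/day, launches between 07:00 and 23:30) with
  Zipf app choice over a configurable catalog. App features act as the
  negative controls in importance rankings.

## Sampling and missingness

Logging is sampled, not continuous: a Poisson number of battery-change
events per day (mean 100) defines the schedule; each scheduled event is
unlogged with probability `missing_interval_rate` (default 0.02) — these
are the "missing log intervals" the day filter counts. Screen and
internet states are observed at retained sampling events and recorded
only on change, so the stored log satisfies the alternation invariant of
real lock/unlock logs; app launches survive only if their covering
sampling event logged. Sample-and-hold reconstruction of a process with
dwell times comparable to the sampling gap adds day-level measurement
noise to the entropy features; empirically this noise has an SD near 0.10
at 100 events/day with regression slope ~1 against the generated target,
and it is carried as an explicit term (`entropy_meas_sd`) in the effect
calibration below.

## Calibrating the effect size

`calibrate_entropy_effect()` solves in closed form for the standardized
shift delta such that the population correlation between the
window-pooled screen normalized entropy and the PHQ-8 total equals a
target r (default 0.14). All ingredients are analytic: the
label-total covariance and outcome SD come from the configured total
pmf, and the pooled-feature variance is
`sigma_b^2 + (sigma_w^2 + sigma_m^2)/n_bar + delta^2 sigma_e^2 v` with
`n_bar = 13` expected retained days per window and `v` the label
variance. No simulation is involved, so the default `entropy_effect` is a
deterministic function of the configuration.

# Preprocessing and features

Timestamps are converted to participant-local time; every event belongs
to exactly one local calendar day. Conventions, chosen to be
deterministic and conservative toward inactivity:

* state between logs is carried forward; before any log a participant is
  off/disconnected;
* the hourly modal state is the state occupying the most minutes of the
  hour, ties breaking toward off/disconnected;
* days with 10 or more missing log intervals are excluded, and responses
  need at least 8 retained days in their window;
* the assessment window is the 14 calendar days ending on the response
  date inclusive (the PHQ-8 asks about the past two weeks including
  "today"); a config flag can exclude the response day.

The 22 day-level markers (`feature_names()`) are: 6 counts, 6 entropies
(raw and normalized, natural log, for screen/internet/app), 3 regularity
indices, 5 epoch-count SDs, and first/last app-use minutes. Entropy uses
state-duration proportions for screen and internet and per-app launch
frequencies for apps; a single-state day has entropy 0 and normalized
entropy 0 (the 0/0 limit resolved by continuity). The regularity index of
two days is the mean over the 24 hours of the product of hourly values
rescaled to [-0.5, 0.5] (binary states map to +/-0.5; app hourly
distinct-app counts are rescaled linearly by the maximum over the day
pair, a zero pair scoring 0). No extra normalizing constant is applied,
so the index lives in [-0.25, 0.25]; downstream statistics are invariant
to that scale choice. A day's regularity feature averages its pair scores
against the other retained days of the same ISO-8601 week and is missing
for a day alone in its week. Epoch SDs are n-1 sample SDs over the four
6-hour day epochs (night 0-5, morning 6-11, afternoon 12-17, evening
18-23).

Pooling onto a response averages count, entropy, regularity and app-time
features over the window's days (missing values dropping out of their
feature's mean) and combines SD features as the
degrees-of-freedom-weighted pooled SD, which with equal epochs per day is
the root mean daily variance. Exact duplicate rows (all features plus
label) are removed.

# Statistics

`pearson_with_holm()` correlates each feature with the total on
pairwise-complete rows and applies the Holm step-down adjustment. Holm
controls the family-wise error rate, not the false discovery rate, and is
implemented as named. `lmm_associations()` fits, per feature and per
imputed data set, `total ~ standardized feature + (1 | participant)` and
pools by Rubin's rules (`rubin_pool()`), with large-sample Wald p-values
(the small-sample degrees-of-freedom correction is omitted at these
cohort sizes) and Benjamini-Hochberg adjustment. Imputation is
single-level predictive mean matching (`pmm_impute()`, 20 imputations,
5 donors, bootstrap-perturbed OLS predictions); in this pipeline
missingness arises mainly from regularity features of days without week
peers.

One methodological note that matters for testing: on pooled
repeated-measures samples, the sampling variance of a Pearson r is
inflated by participant clustering (both the feature's participant
baseline and the labels cluster). `pearson_cluster_se()` provides a
delete-one-participant jackknife SE for honest uncertainty statements;
the package's own recovery checks use it, and the naive i.i.d. SE should
not be used on such data.

# Classification harness

`nested_cv()` evaluates random forest, RBF-kernel SVM, gradient-boosted
trees, k-nearest neighbors and L2-penalized logistic regression with
stratified 10-fold outer evaluation and stratified 3-fold inner grid
search selecting hyperparameters by macro-averaged F1. SMOTE
(reimplemented in `smote()`: minority interpolation toward one of the 5
nearest minority neighbors) balances training partitions *inside* each
split only; the driver asserts train/test disjointness per fold and logs
the audit. Features are standardized with training-fold statistics for
the distance/margin learners (SVM, KNN, LR) and left raw for trees.
Probabilities feed a midrank AUC; hard predictions at 0.5 feed accuracy,
positive-class precision/recall/F1 and Cohen's kappa. Permutation
importance is the AUC drop when one feature column is shuffled within the
held-out fold, averaged over repeats and outer folds.

Two baselines frame the classifier numbers: a random weighted classifier
(`rwc_baseline()`, 10,000 prediction vectors drawn i.i.d. from the
empirical class distribution) and a decision tree restricted to one-hot
age group and gender (`dt_baseline()`). Under the i.i.d. multinomial
definition the RWC's expected kappa is 0, its midrank AUC of hard
predictions is exactly (sensitivity + specificity)/2 = 0.5 in
expectation, and both precision and recall concentrate on the prevalence;
the package intentionally targets only the distribution-free kappa and
AUC rows of that baseline.

Fold assignment is record-level by default, which reproduces the
protocol commonly used with pooled repeated measures — and also its
leakage risk: with high-ICC outcomes, a classifier can re-identify a
participant seen in training and recall their label, inflating AUC even
when the label is independent of every feature. `cv_config(group_folds =
TRUE)` provides participant-grouped folds that remove this route. The
package's null-calibration test is therefore run on cohorts configured
for one response per participant (14-day follow-up), which isolates what
that test is meant to verify — that SMOTE and the grid search never touch
test rows — while a separate check confirms that grouped folds never beat
record-level folds on high-ICC repeated-measures data with no true
effect.

# Problem sizes and numerical choices

The shipped checks use cohort sizes chosen to balance statistical
resolution against desk-scale runtimes: 940 participants (about 1,370
pooled samples) for effect-size recovery, 5 replicates of 200
single-response participants for null calibration, 10 replicates of 100
participants for importance ranking, and 3 replicates of 120 participants
for the grouped-vs-record-level comparison, with single-point
hyperparameter grids in the harness checks (the grids themselves are
configuration, not conclusions). Recovery tolerances are 3 estimated
standard errors of the quantity under its actual sampling design
(cluster-jackknife for r, Rubin total variance for the pooled slope,
binomial for rates). Entropy inversion uses a 4096-point monotone
interpolation of the binary entropy function (~1e-6 accuracy); all
entropies use natural logarithms (normalization cancels the base); ties
in AUC use midranks; tie-breaks in hourly modal states go toward
inactivity.

# Limitations

The generator emulates the *design* of a battery-sampled sensing study,
not the texture of real phone use: no weekday/weekend structure, no
circadian app mixtures, no travel or timezone changes, no
battery-physics correlation between sampling density and behavior, and
independence between behavioral baselines and demographics. Passing
recovery tests therefore demonstrates that the pipeline measures what it
injects at realistic noise levels — not that real cohorts carry such
signals. Daylight-saving transitions are handled by the platform's
timezone database; a day spanning a transition simply has 23 or 25 local
hours and its few minutes of spillover are not specially corrected.
Observed-total ICC and real-data classifier metrics are not reproduction
targets, since the original cohort is not available.
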