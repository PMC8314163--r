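# Nested cross-validation harness, baselines, importance.

small_grids <- function() {
  list(
    rf = data.frame(ntree = 60L, maxnodes = NA),
    svm = data.frame(cost = 1, gamma = NA),
    xgb = data.frame(max_depth = 3L, eta = 0.3, nrounds = 40L),
    knn = data.frame(k = 5L),
    lr = data.frame(lambda = 0.01),
    dt = data.frame(cp = 0.01, maxdepth = 4L)
  )
}

separable_samples <- function(n = 140, seed = 30) {
  set.seed(seed)
  x <- rnorm(n)
  tibble::tibble(
    participant_id = sprintf("p%04d", seq_len(n)),
    screen_normEntropy = x,
    net_regIndex = rnorm(n),
    app_count = rnorm(n),
    label = as.integer(x > stats::quantile(x, 0.75))
  )
}

test_that("nested CV separates separable data and is seed-deterministic", {
  df <- separable_samples()
  cv <- cv_config(
    outer_folds = 5, inner_folds = 2, classifiers = c("rf", "lr"),
    grids = small_grids(), seed = 11
  )
  rep1 <- nested_cv(df, cv, importance = FALSE)
  auc <- rep1$summary[rep1$summary$metric == "auc", ]
  expect_true(all(auc$mean > 0.9))
  kap <- rep1$summary[rep1$summary$metric == "kappa", ]
  expect_true(all(kap$mean > 0.6))
  expect_equal(nrow(rep1$metrics), 2L * 5L) # classifiers x folds
  rep2 <- nested_cv(df, cv, importance = FALSE)
  expect_identical(rep1$metrics, rep2$metrics)
})

test_that("the grid search selects hyperparameters by inner macro-F1", {
  df <- separable_samples(160, seed = 31)
  grids <- small_grids()
  grids$knn <- data.frame(k = c(1L, 5L, 25L))
  cv <- cv_config(
    outer_folds = 4, inner_folds = 2, classifiers = "knn",
    grids = grids, seed = 12
  )
  rep <- nested_cv(df, cv, importance = FALSE)
  expect_equal(nrow(rep$selected), 4L)
  expect_true(all(rep$selected$k %in% c(1L, 5L, 25L)))
  expect_true(all(rep$selected$inner_macro_f1 > 0.5))
})

test_that("training partitions stay disjoint from test folds", {
  df <- separable_samples(100, seed = 32)
  cv <- cv_config(
    outer_folds = 5, inner_folds = 2, classifiers = "lr",
    grids = small_grids(), seed = 13
  )
  rep <- nested_cv(df, cv, importance = FALSE)
  expect_true(all(rep$audit$disjoint))
  expect_equal(sum(rep$audit$n_test), nrow(df))
  # fold partition covers every row exactly once
  expect_equal(sort(unname(unlist(tapply(seq_len(nrow(df)), rep$folds, identity)))), seq_len(nrow(df)))
})

test_that("permutation importance isolates the informative feature", {
  df <- separable_samples(220, seed = 33)
  cv <- cv_config(
    outer_folds = 4, inner_folds = 2, classifiers = "lr",
    grids = small_grids(), permutation_repeats = 5, seed = 14
  )
  rep <- nested_cv(df, cv, importance = TRUE)
  imp <- rep$importance
  main <- imp$importance[imp$feature == "screen_normEntropy"]
  noise <- imp$importance[imp$feature != "screen_normEntropy"]
  # near-perfect model: shuffling the label-defining feature costs ~0.5 AUC
  expect_gt(main, 0.3)
  expect_true(all(abs(noise) < 0.05))

  # a duplicated informative feature splits credit with its copy
  df2 <- df
  df2$copy <- df2$screen_normEntropy
  rep2 <- nested_cv(
    df2, cv,
    features = c("screen_normEntropy", "copy", "net_regIndex", "app_count")
  )
  imp2 <- rep2$importance
  expect_lt(
    imp2$importance[imp2$feature == "screen_normEntropy"], main
  )
})

test_that("the random weighted baseline matches its analytic expectations", {
  y <- rep(c(1L, 0L), c(40L, 160L))
  rwc <- rwc_baseline(y, n_draws = 4000, seed = 15)
  get <- function(m) rwc$mean[rwc$metric == m]
  se <- function(m) rwc$se[rwc$metric == m]
  expect_lt(abs(get("kappa")), 3 * se("kappa"))
  expect_lt(abs(get("auc") - 0.5), 3 * se("auc"))
  # under the i.i.d. multinomial predictor, recall and precision both
  # concentrate on the prevalence
  expect_lt(abs(get("recall") - 0.2), 3 * se("recall"))
  expect_lt(abs(get("precision") - 0.2), 3 * se("precision"))
  expect_error(rwc_baseline(rep(1L, 10)), "both classes")
})

test_that("RWC per-draw metrics agree with the generic metric set", {
  set.seed(16)
  y <- rbinom(120, 1, 0.25)
  # one draw reproduced manually through metric_set
  rwc <- rwc_baseline(y, n_draws = 1, seed = 17)
  pred <- depsense:::with_seed(17, rbinom(length(y), 1L, mean(y)))
  m <- metric_set(y, pred)
  for (nm in rwc$metric) {
    expect_equal(rwc$mean[rwc$metric == nm], m[[nm]], tolerance = 1e-12)
  }
})

test_that("the demographic decision-tree baseline tracks its signal", {
  cfg <- tiny_config(n = 60, seed = 61)
  prof <- generate_population(cfg)
  base <- tibble::tibble(participant_id = rep(prof$participant_id, 3))
  aug <- one_hot_demographics(base, prof)
  # label a deterministic function of age group -> near-perfect tree
  aug$label <- as.integer(aug[["age_group_25_34"]] == 1 | aug[["age_group_18_24"]] == 1)
  cv <- cv_config(
    outer_folds = 4, inner_folds = 2, grids = small_grids(),
    classifiers = "dt", seed = 18
  )
  rep <- dt_baseline(aug, cv)
  auc <- rep$summary[rep$summary$metric == "auc", ]
  expect_gt(auc$mean, 0.95)
  # demographics independent of the label -> chance-level tree
  aug$label <- depsense:::with_seed(19, rbinom(nrow(aug), 1, 0.3))
  rep0 <- dt_baseline(aug, cv)
  auc0 <- rep0$summary[rep0$summary$metric == "auc", ]
  expect_lt(abs(auc0$mean - 0.5), 0.12)
  expect_error(dt_baseline(base, cv), "one-hot")
})
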