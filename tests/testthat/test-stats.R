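# Correlation/association statistics.

test_that("Holm and BH match the hand step-down/step-up procedures", {
  expect_equal(holm_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))

  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    h <- holm_adjust(p)
    b <- bh_adjust(p)
    expect_equal(h, holm_oracle(p))
    expect_equal(b, bh_oracle(p))
    expect_true(all(h >= b - 1e-15)) # Holm >= BH >= raw elementwise
    expect_true(all(b >= p - 1e-15))
    # monotone nondecreasing in sorted order
    expect_true(all(diff(h[order(p)]) >= -1e-15))
    expect_true(all(diff(b[order(p)]) >= -1e-15))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "probability")
})

test_that("the Pearson screen handles self-correlation and constants", {
  out <- run_small_pipeline(tiny_config(n = 8, seed = 41))
  pl <- out$pooled
  pl$self <- pl$phq8_total
  pl$const <- 1
  res <- suppressWarnings(
    pearson_with_holm(pl, features = c("self", "const", "screen_normEntropy"))
  )
  expect_equal(res$estimate[res$feature == "self"], 1, tolerance = 1e-12)
  expect_true(is.na(res$estimate[res$feature == "const"]))
  expect_warning(
    pearson_with_holm(pl, features = c("const", "screen_normEntropy")),
    "constant"
  )
  ok <- !is.na(res$p_raw)
  expect_true(all(res$p_adjusted[ok] >= res$p_raw[ok]))
})

test_that("ICC estimators agree and recover known variance components", {
  # degenerate: no within-group variation
  y <- rep(c(1, 5, 9), each = 4)
  g <- rep(1:3, each = 4)
  expect_equal(icc_components(y, g, method = "anova")$icc, 1)

  # null: i.i.d. outcome
  set.seed(6)
  y0 <- rnorm(2000)
  g0 <- rep(1:100, each = 20)
  expect_lt(icc_components(y0, g0, method = "reml")$icc, 0.05)

  # recovery: between 3, within 1 -> ICC 0.75
  set.seed(7)
  k <- 150
  reps <- 5
  b <- rnorm(k, 0, sqrt(3))
  yy <- rep(b, each = reps) + rnorm(k * reps, 0, 1)
  gg <- rep(seq_len(k), each = reps)
  rml <- icc_components(yy, gg, method = "reml")
  av <- icc_components(yy, gg, method = "anova")
  # simulation SE of the ICC estimate at k=150 groups is ~0.02
  expect_lt(abs(rml$icc - 0.75), 3 * 0.02)
  expect_lt(abs(av$icc - rml$icc), 0.02)
  expect_equal(rml$icc, rml$between_variance / (rml$between_variance + rml$within_variance))

  expect_error(icc_components(1:4, 1:4), ">= 2 groups")
})

test_that("PMM imputation uses observed donors and preserves MCAR means", {
  out <- run_small_pipeline(tiny_config(n = 10, seed = 47))
  pl <- out$pooled[complete.cases(out$pooled[feature_names()]), ]

  # no missingness -> identical copies
  imps <- pmm_impute(pl, m = 3, seed = 1)
  expect_length(imps, 3)
  expect_identical(imps[[1]], pl)

  # single missing cell -> every fill is an observed value of the column
  holed <- pl
  holed$screen_normEntropy[2] <- NA
  imps2 <- pmm_impute(holed, m = 20, seed = 2)
  fills <- vapply(imps2, function(tb) tb$screen_normEntropy[2], numeric(1))
  expect_true(all(fills %in% pl$screen_normEntropy[-2]))

  # MCAR 10%: imputed-column mean close to the complete-data mean
  set.seed(3)
  mcar <- pl
  miss_idx <- sample(nrow(pl), ceiling(0.1 * nrow(pl)))
  mcar$screen_entropy[miss_idx] <- NA
  imps3 <- pmm_impute(mcar, m = 10, seed = 4)
  means <- vapply(imps3, function(tb) mean(tb$screen_entropy), numeric(1))
  se <- sd(pl$screen_entropy) / sqrt(nrow(pl))
  expect_lt(abs(mean(means) - mean(pl$screen_entropy)), 3 * se)

  allna <- pl
  allna$app_entropy <- NA_real_
  expect_error(pmm_impute(allna, m = 2), "entirely missing")
})

test_that("Rubin pooling reproduces the hand arithmetic", {
  # m = 2, estimates (1, 3), within variance 1 -> total 1 + 1.5 * 2 = 4
  pooled <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(pooled$estimate, 2)
  expect_equal(pooled$se^2, 4)
  # all imputations identical -> between = 0, se = sqrt(W)
  degenerate <- rubin_pool(rep(1.7, 5), rep(0.09, 5))
  expect_equal(degenerate$between, 0)
  expect_equal(degenerate$se, 0.3)
})

test_that("the pooled mixed model recovers a known standardized slope", {
  set.seed(99)
  k <- 120
  reps <- 3
  g <- rep(sprintf("p%03d", seq_len(k)), each = reps)
  x <- rnorm(k * reps)
  y <- 0.5 * x + rep(rnorm(k, 0, 1), each = reps) + rnorm(k * reps, 0, 0.7)
  tb <- tibble::tibble(participant_id = g, phq8_total = y, f = x)
  res <- fit_bivariate_lmm_pooled(rep(list(tb), 3), "f")
  # slope on the standardized scale: 0.5 * sd(x)
  expect_lt(abs(res$estimate - 0.5 * sd(x)), 3 * res$se)
  expect_equal(res$method, "lmm")
  expect_true(res$p_raw < 0.001)
})

test_that("the association screens share one family-adjustment contract", {
  out <- run_small_pipeline(tiny_config(n = 10, seed = 53))
  pl <- out$pooled[complete.cases(out$pooled[feature_names()]), ]
  imps <- pmm_impute(pl, m = 2, seed = 5)
  assoc <- lmm_associations(imps, features = c("screen_normEntropy", "app_count", "net_entropy"))
  expect_equal(nrow(assoc), 3L)
  ok <- !is.na(assoc$p_raw)
  expect_true(all(assoc$p_adjusted[ok] >= assoc$p_raw[ok]))
  expect_true(all(assoc$n_imputations[ok] == 2))
  td <- tidy(assoc)
  expect_named(
    td, c("term", "estimate", "std.error", "p.value", "p.adjusted", "method")
  )
})
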