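# Generator: configuration, population, event streams, PHQ-8 outcomes.

test_that("config validation rejects malformed inputs", {
  expect_error(synth_config(days_range = c(5, 20)), "at least 8")
  expect_error(synth_config(missing_interval_rate = 1.2), "probability")
  bad <- default_demographic_marginals()
  bad$gender <- c(female = 0.5, male = 0.6)
  expect_error(synth_config(demographic_marginals = bad), "sum to 1")
  expect_error(
    synth_config(demographic_marginals = list(0.5)),
    "named list"
  )
})

test_that("population sampling matches marginals and is deterministic", {
  expect_equal(nrow(generate_population(tiny_config(n = 0))), 0L)

  cfg <- synth_config(n_participants = 3000, seed = 42)
  prof <- generate_population(cfg)
  p_male <- mean(prof$gender == "male")
  se <- sqrt(0.868 * 0.132 / 3000)
  expect_lt(abs(p_male - 0.868), 3 * se)
  p_2534 <- mean(prof$age_group == "25-34")
  expect_lt(abs(p_2534 - 0.324), 3 * sqrt(0.324 * 0.676 / 3000))
  expect_true(all(prof$timezone %in% OlsonNames()))

  prof2 <- generate_population(synth_config(n_participants = 3000, seed = 42))
  expect_identical(prof, prof2)
})

test_that("PHQ-8 total distribution hits its moments and prevalence exactly", {
  pmf <- phq8_total_pmf(0.1681)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  expect_equal(sum(pmf[11:25]), 0.1681, tolerance = 1e-12)
  mu <- sum(0:24 * pmf)
  expect_lt(abs(mu - 5.19), 0.6)

  # Monte-Carlo prevalence through the latent quantile transform
  set.seed(9)
  z <- rnorm(10000)
  totals <- depsense:::phq8_total_from_latent(z, pmf)
  expect_true(all(totals >= 0 & totals <= 24))
  frac <- mean(totals >= 10)
  expect_lt(abs(frac - 0.1681), 3 * sqrt(0.1681 * 0.8319 / 10000))
})

test_that("PHQ-8 items are capped at 3 and sum to the total", {
  cfg <- tiny_config(n = 1)
  prof <- generate_population(cfg)
  set.seed(4)
  lo <- simulate_phq8(prof, -10, as.Date("2018-03-14"), cfg)
  expect_equal(lo$phq8_total, 0L)
  expect_true(all(as.numeric(lo[paste0("item_", 1:8)]) == 0))
  hi <- simulate_phq8(prof, 10, as.Date("2018-03-14"), cfg)
  expect_equal(hi$phq8_total, 24L)
  expect_true(all(as.numeric(hi[paste0("item_", 1:8)]) == 3))
  for (z in c(-0.5, 0.3, 1.1)) {
    r <- simulate_phq8(prof, z, as.Date("2018-03-14"), cfg)
    items <- as.numeric(r[paste0("item_", 1:8)])
    expect_true(all(items %in% 0:3))
    expect_equal(sum(items), r$phq8_total)
  }
})

test_that("event logs respect ordering, alternation and the sampling schedule", {
  cfg <- tiny_config(n = 2, seed = 7, missing_interval_rate = 0.05)
  prof <- generate_population(cfg)
  ev <- simulate_participant_days(prof[1, ], cfg, n_days = 12)

  expect_true(!is.unsorted(ev$timestamp_utc))
  for (s in c("screen", "internet")) {
    v <- ev$value[ev$stream == s]
    expect_true(all(v[-1] != v[-length(v)]))
  }
  expect_true(all(ev$battery_level >= 0 & ev$battery_level <= 100))

  sch <- attr(ev, "schedule")
  expect_equal(nrow(sch), 12L)
  expect_true(all(sch$missing_intervals <= sch$scheduled))
  # missing fraction compatible with the configured rate
  frac <- sum(sch$missing_intervals) / sum(sch$scheduled)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / sum(sch$scheduled)))

  none <- simulate_participant_days(
    prof[2, ], synth_config(n_participants = 2, seed = 7, missing_interval_rate = 0),
    n_days = 10
  )
  expect_true(all(attr(none, "schedule")$missing_intervals == 0L))

  # determinism: same profile/config twice
  ev2 <- simulate_participant_days(prof[1, ], cfg, n_days = 12)
  expect_identical(ev, ev2)
})

test_that("seed determinism yields byte-identical serialized studies", {
  s1 <- simulate_study(tiny_config(n = 5, seed = 31))
  s2 <- simulate_study(tiny_config(n = 5, seed = 31))
  expect_identical(
    serialize(s1, NULL, version = 3L), serialize(s2, NULL, version = 3L)
  )
  s3 <- simulate_study(tiny_config(n = 5, seed = 32))
  expect_false(identical(s1$events, s3$events))
})

test_that("the depressed-window shift lands on the day-level entropy targets", {
  # The generated target entropies shift by exactly effect * sigma_e
  # (before clamping); the measured features track the targets with
  # regression slope ~ 1.
  cfg <- synth_config(
    n_participants = 50, seed = 13, entropy_effect = 0.5,
    nonlinear_effect_flag = FALSE
  )
  sigma_e <- sqrt(cfg$entropy_between_sd^2 + cfg$entropy_within_sd^2)
  st <- simulate_study(cfg)
  td <- st$truth_days
  fe <- lm(
    target_norm_entropy ~ depressed_day + factor(participant_id),
    data = td
  )
  co <- summary(fe)$coefficients["depressed_dayTRUE", ]
  expect_lt(abs(co[["Estimate"]] - 0.5 * sigma_e), 3 * co[["Std. Error"]])

  days <- filter_days(localize_and_segment(st$events, st$profiles, st$schedule))
  ft <- extract_features(days)
  m <- dplyr::inner_join(ft, td, by = c("participant_id", "local_date"))
  slope <- lm(screen_normEntropy ~ target_norm_entropy, data = m)
  co2 <- summary(slope)$coefficients["target_norm_entropy", ]
  expect_lt(abs(co2[["Estimate"]] - 1), max(3 * co2[["Std. Error"]], 0.06))
})

test_that("group differences are monotone in the entropy effect and null at zero", {
  diffs <- vapply(c(0, 0.7, 1.4), function(eff) {
    cfg <- synth_config(
      n_participants = 40, seed = 77, entropy_effect = eff,
      nonlinear_effect_flag = FALSE
    )
    st <- simulate_study(cfg)
    td <- st$truth_days
    if (sum(td$depressed_day) < 5) return(NA_real_)
    fe <- lm(target_norm_entropy ~ depressed_day + factor(participant_id), data = td)
    coef(fe)[["depressed_dayTRUE"]]
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))

  # null case: with zero effect the day streams are label-exchangeable
  cfg0 <- synth_config(
    n_participants = 40, seed = 78, entropy_effect = 0,
    nonlinear_effect_flag = FALSE
  )
  st0 <- simulate_study(cfg0)
  fe0 <- lm(
    target_norm_entropy ~ depressed_day + factor(participant_id),
    data = st0$truth_days
  )
  co0 <- summary(fe0)$coefficients["depressed_dayTRUE", ]
  expect_lt(abs(co0[["Estimate"]]), 3 * co0[["Std. Error"]])
})

test_that("follow-up lengths respect the configured range and skewness", {
  cfg <- synth_config(seed = 5)
  set.seed(11)
  d <- draw_followup_days(5000, cfg)
  expect_true(all(d >= 8 & d <= 86))
  expect_lt(abs(mean(d) - 22.1), 1.5)
  expect_gt(mean(d <= 14), 0.4) # right-skewed: many short participants
})

test_that("configs round-trip through YAML", {
  cfg <- tiny_config(n = 9, seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, path)
  cfg2 <- read_synth_config(path)
  expect_equal(cfg$demographic_marginals, cfg2$demographic_marginals)
  expect_equal(cfg$entropy_effect, cfg2$entropy_effect)
  e1 <- simulate_study(cfg)$events
  e2 <- simulate_study(cfg2)$events
  expect_identical(e1$value, e2$value)
  expect_identical(e1$stream, e2$stream)
  expect_equal(as.numeric(e1$timestamp_utc), as.numeric(e2$timestamp_utc))
})
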