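# The 22 day-level markers: entropy, regularity, epoch SDs.

test_that("Shannon entropy matches direct summation", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_equal(shannon_entropy(c(0.25, 0.75)), 0.5623, tolerance = 1e-4)
  expect_equal(shannon_entropy(c(0.25, 0.75)), brute_entropy(c(0.25, 0.75)))
  expect_error(shannon_entropy(c(0.2, 0.7)), "sum to 1")
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
})

test_that("normalized entropy is entropy over log N, with single-state 0", {
  expect_equal(normalized_entropy(c(0.5, 0.5)), 1)
  expect_equal(normalized_entropy(c(1, 0)), 0)
  expect_equal(normalized_entropy(1), 0)
  expect_equal(normalized_entropy(c(0.25, 0.75)), 0.8113, tolerance = 1e-4)
})

test_that("regularity index honors its closed form, bounds and symmetries", {
  all_pos <- rep(0.5, 24)
  expect_equal(regularity_index_pair(all_pos, all_pos), 0.25)
  expect_equal(regularity_index_pair(all_pos, -all_pos), -0.25)
  half <- rep(c(0.5, -0.5), each = 12)
  expect_equal(regularity_index_pair(half, all_pos), 0)
  expect_error(regularity_index_pair(rep(0.5, 23), all_pos), "length 24")
  expect_error(regularity_index_pair(rep(0.7, 24), all_pos), "rescaled")

  set.seed(21)
  for (i in 1:25) {
    a <- runif(24, -0.5, 0.5)
    b <- runif(24, -0.5, 0.5)
    r <- regularity_index_pair(a, b)
    expect_equal(r, regularity_index_pair(b, a)) # symmetric
    expect_true(r >= -0.25 && r <= 0.25) # bounded
    perm <- sample(24)
    expect_equal(r, regularity_index_pair(a[perm], b[perm])) # hour relabeling
    expect_equal(r, brute_regularity(a, b))
  }
})

test_that("app-count rescaling is invariant to common scaling", {
  set.seed(3)
  a <- rpois(24, 2)
  b <- rpois(24, 2)
  rs1 <- rescale_count_pair(a, b)
  rs3 <- rescale_count_pair(3 * a, 3 * b)
  expect_equal(
    regularity_index_pair(rs1$a, rs1$b), regularity_index_pair(rs3$a, rs3$b)
  )
  zero <- rescale_count_pair(rep(0, 24), rep(0, 24))
  expect_true(zero$degenerate)
})

test_that("epoch SD is the n-1 sample SD of the four epochs", {
  expect_equal(epoch_count_sd(c(5, 5, 5, 5)), 0)
  expect_equal(epoch_count_sd(c(0, 0, 0, 12)), 6)
  expect_equal(epoch_count_sd(c(1, 2, 3, 4)), 1.2910, tolerance = 1e-4)
  expect_error(epoch_count_sd(1:3), "4 epoch")
})

test_that("daily regularity averages pair scores over same-week peers", {
  on24 <- rep("on", 24)
  off24 <- rep("off", 24)
  split_day <- rep(c("on", "off"), each = 12)
  target <- make_day(hourly_screen = on24)
  peers <- dplyr::bind_rows(
    make_day(local_date = as.Date("2018-04-03"), hourly_screen = on24),
    make_day(local_date = as.Date("2018-04-04"), hourly_screen = split_day),
    make_day(local_date = as.Date("2018-04-05"), hourly_screen = off24)
  )
  # pair scores 0.25, 0, -0.25 -> mean 0
  expect_equal(daily_regularity(target, peers, "screen"), 0)
  expect_true(is.na(daily_regularity(target, peers[0, ], "screen")))
})

test_that("day features cover the canonical 22 with the documented conventions", {
  days <- dplyr::bind_rows(
    # Monday: screen half on, one app launched 4 times at 07:30..22:15
    make_day(
      local_date = as.Date("2018-04-02"), screen_on_minutes = 720,
      app_freqs = c(mail = 4L), app_first = 450, app_last = 1335,
      epoch_counts = list(screen_on = c(0L, 0L, 0L, 12L))
    ),
    # Tuesday: same week peer with an identical hourly screen pattern
    make_day(local_date = as.Date("2018-04-03"), screen_on_minutes = 360),
    # next ISO week: single day, regularity must be missing
    make_day(local_date = as.Date("2018-04-09"))
  )
  ft <- extract_features(days)
  expect_identical(setdiff(names(ft), c("participant_id", "local_date")), feature_names())
  expect_equal(nrow(ft), 3L)

  expect_equal(ft$screen_normEntropy[1], 1) # 12h on / 12h off
  expect_equal(ft$app_entropy[1], 0) # single app
  expect_equal(ft$app_normEntropy[1], 0)
  expect_equal(ft$app_distinctCount[1], 1)
  expect_equal(ft$app_firstUseMinutes[1], 450)
  expect_equal(ft$app_lastUseMinutes[1], 1335)
  expect_equal(ft$screen_onCountSD[1], 6) # epochs (0,0,0,12)
  # identical hourly patterns within the week -> maximal regularity
  expect_equal(ft$screen_regIndex[1], 0.25)
  expect_true(is.na(ft$screen_regIndex[3])) # no peers in that week
  expect_true(is.na(ft$app_firstUseMinutes[2]))
})

test_that("generated feature tables are complete and within bounds", {
  out <- run_small_pipeline(tiny_config(n = 6, seed = 19))
  ft <- out$features
  expect_true(all(feature_names() %in% names(ft)))
  expect_equal(ncol(ft), 24L) # ids + 22 features
  expect_true(all(ft$screen_entropy >= 0, na.rm = TRUE))
  expect_true(all(ft$screen_normEntropy >= 0 & ft$screen_normEntropy <= 1, na.rm = TRUE))
  reg <- unlist(ft[c("screen_regIndex", "net_regIndex", "app_regIndex")])
  expect_true(all(reg >= -0.25 & reg <= 0.25, na.rm = TRUE))
  sds <- unlist(ft[c("screen_onCountSD", "app_countSD")])
  expect_true(all(sds >= 0, na.rm = TRUE))
  both <- !is.na(ft$app_firstUseMinutes)
  expect_true(all(ft$app_firstUseMinutes[both] <= ft$app_lastUseMinutes[both]))
})
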