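# Localization, day segmentation, inclusion filters.

test_that("hourly modal state follows majority duration with ties toward off", {
  # screen on 09:10, off 09:50 -> hour 9 is "on" (40 vs 20 minutes)
  ev <- make_events(
    "p01",
    c("2018-04-02 08:00:00", "2018-04-02 09:10:00", "2018-04-02 09:50:00"),
    "screen", c("off", "on", "off")
  )
  days <- localize_and_segment(ev, utc_profile())
  hs <- days$hourly_screen[[1]]
  expect_equal(hs[10], "on")
  expect_equal(hs[9], "off")
  # exactly 30/30 split ties to off
  ev2 <- make_events(
    "p01",
    c("2018-04-02 08:00:00", "2018-04-02 09:00:00", "2018-04-02 09:30:00"),
    "screen", c("off", "on", "off")
  )
  hs2 <- localize_and_segment(ev2, utc_profile())$hourly_screen[[1]]
  expect_equal(hs2[10], "off")
})

test_that("durations use carry-forward and default to off before any log", {
  ev <- make_events(
    "p01", c("2018-04-02 06:00:00", "2018-04-02 18:00:00"),
    "screen", c("on", "off")
  )
  days <- localize_and_segment(ev, utc_profile())
  expect_equal(days$screen_pos_minutes, 720) # on 06:00-18:00 only
  expect_equal(days$net_pos_minutes, 0) # never connected
})

test_that("timezone conversion assigns events to shifted local dates", {
  # all events in one UTC day; UTC+12 pushes the evening into the next day
  ev <- make_events(
    "p01", c("2018-04-02 06:00:00", "2018-04-02 20:00:00"),
    "screen", c("on", "off"), tz = "UTC"
  )
  days <- localize_and_segment(ev, utc_profile(tz = "Etc/GMT-12"))
  expect_equal(
    days$local_date, as.Date(c("2018-04-02", "2018-04-03"))
  )
})

test_that("days without app events have missing first/last use", {
  ev <- make_events("p01", "2018-04-02 08:00:00", "screen", "on")
  days <- localize_and_segment(ev, utc_profile())
  expect_true(is.na(days$app_first_minute))
  expect_true(is.na(days$app_last_minute))
  expect_equal(days$app_distinct_count, 0L)
})

test_that("segmentation conserves events and matches the generator schedule", {
  cfg <- tiny_config(n = 6, seed = 55, missing_interval_rate = 0.08)
  study <- simulate_study(cfg)
  days <- localize_and_segment(study$events, study$profiles, study$schedule)

  # every event lands in exactly one local day
  count_cols <- paste0(
    "count_", c("screen_on", "screen_off", "net_connected", "net_disconnected", "app_use")
  )
  expect_equal(sum(as.matrix(days[count_cols])), nrow(study$events))

  # missing-interval counts equal the generator's counts exactly
  joined <- dplyr::inner_join(
    days, study$schedule,
    by = c("participant_id", "local_date"), suffix = c("", "_gen")
  )
  expect_gt(nrow(joined), 0)
  expect_identical(joined$missing_intervals, joined$missing_intervals_gen)
})

test_that("unknown timezones and empty inputs are handled", {
  ev <- make_events("p01", "2018-04-02 08:00:00", "screen", "on")
  prof <- utc_profile(tz = "Mars/Olympus")
  expect_error(localize_and_segment(ev, prof), "timezone")
  expect_equal(nrow(localize_and_segment(ev[0, ], utc_profile())), 0L)
})

test_that("day filter applies the 10-missing-interval rule at its boundary", {
  days <- dplyr::bind_rows(
    make_day(local_date = as.Date("2018-04-02"), missing_intervals = 9L),
    make_day(local_date = as.Date("2018-04-03"), missing_intervals = 10L),
    make_day(local_date = as.Date("2018-04-04"), missing_intervals = 11L),
    make_day(local_date = as.Date("2018-04-05"), missing_intervals = 0L)
  )
  kept <- filter_days(days)
  expect_equal(kept$local_date, as.Date(c("2018-04-02", "2018-04-05")))
  expect_identical(filter_days(kept), kept) # idempotent
})

test_that("response filter requires 8 retained days in the 14-day window", {
  resp <- tibble::tibble(
    participant_id = "p01",
    response_date = as.Date("2018-04-14"),
    phq8_total = 5L
  )
  mk_days <- function(n) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_day(local_date = as.Date("2018-04-14") - i + 1L)
    }))
  }
  expect_equal(nrow(filter_responses(resp, mk_days(8))), 1L)
  expect_equal(nrow(filter_responses(resp, mk_days(7))), 0L)
  # participant with no days at all
  none <- mk_days(8)
  none$participant_id <- "p99"
  expect_equal(nrow(filter_responses(resp, none)), 0L)
  # days outside the window do not count
  old <- mk_days(8)
  old$local_date <- old$local_date - 30L
  expect_equal(nrow(filter_responses(resp, old)), 0L)
})

test_that("missing intervals can be inferred from log gaps", {
  # regular 10-minute sampling; logs jump from minute 400 to 470, so the
  # six scheduled events at 410..460 went unlogged
  times <- as.POSIXct("2018-04-02 00:05:00", tz = "UTC") +
    60 * c(seq(0, 400, by = 10), seq(470, 1430, by = 10))
  ev <- tibble::tibble(
    participant_id = "p01", timestamp_utc = times,
    stream = "screen", value = rep_len(c("on", "off"), length(times)),
    battery_level = 50L
  )
  inf <- infer_missing_intervals(ev, utc_profile())
  expect_equal(nrow(inf), 1L)
  expect_equal(inf$missing_intervals, 6L)
})
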