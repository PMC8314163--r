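# Shared fixtures built in code.

# Small but complete study config; effects on by default.
tiny_config <- function(n = 15, seed = 101, ...) {
  synth_config(n_participants = n, seed = seed, ...)
}

# Generate study -> retained days -> features -> pooled samples.
run_small_pipeline <- function(config) {
  study <- simulate_study(config)
  days <- filter_days(localize_and_segment(study$events, study$profiles, study$schedule))
  responses <- filter_responses(study$responses, days)
  features <- extract_features(days)
  pooled <- deduplicate_samples(pool_windows(features, responses))
  list(
    study = study, days = days, responses = responses,
    features = features, pooled = pooled
  )
}

# Hand-built day-summary row compatible with extract_features().
make_day <- function(participant_id = "p01",
                     local_date = as.Date("2018-04-02"),
                     screen_on_minutes = 720,
                     net_connected_minutes = 1200,
                     hourly_screen = rep(c("off", "on"), each = 12),
                     hourly_net = rep("connected", 24),
                     hourly_app_distinct = rep(0L, 24),
                     epoch_counts = list(),
                     app_freqs = integer(0),
                     app_first = NA_real_, app_last = NA_real_,
                     missing_intervals = 0L) {
  row <- tibble::tibble(
    participant_id = participant_id, local_date = local_date,
    screen_pos_minutes = screen_on_minutes,
    net_pos_minutes = net_connected_minutes,
    hourly_screen = list(hourly_screen),
    hourly_net = list(hourly_net),
    hourly_app_distinct = list(hourly_app_distinct)
  )
  types <- c("screen_on", "screen_off", "net_connected", "net_disconnected", "app_use")
  epochs <- c("night", "morning", "afternoon", "evening")
  for (ty in types) {
    cnt <- if (!is.null(epoch_counts[[ty]])) epoch_counts[[ty]] else rep(0L, 4L)
    for (i in seq_along(epochs)) {
      row[[paste0("epoch_", ty, "_", epochs[i])]] <- cnt[i]
    }
    row[[paste0("count_", ty)]] <- sum(cnt)
  }
  row$app_distinct_count <- length(app_freqs)
  row$app_first_minute <- app_first
  row$app_last_minute <- app_last
  row$app_freqs <- list(app_freqs)
  row$missing_intervals <- missing_intervals
  row
}

# Event-record builder (UTC timestamps from local clock strings).
make_events <- function(participant_id, times, stream, value, tz = "UTC") {
  tibble::tibble(
    participant_id = participant_id,
    timestamp_utc = lubridate::with_tz(as.POSIXct(times, tz = tz), "UTC"),
    stream = stream, value = value, battery_level = 50L
  )
}

utc_profile <- function(participant_id = "p01", tz = "UTC") {
  tibble::tibble(
    participant_id = participant_id, timezone = tz, age_group = "25-34",
    gender = "male", education = "undergraduate", occupation = "professional",
    country = "unknown"
  )
}
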