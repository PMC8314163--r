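#' Simulate a complete smartphone-sensing depression study
#'
#' Orchestrates the full generator: participant profiles, per-participant
#' follow-up periods, latent depression severity evolving as a
#' participant intercept plus an AR(1) process over 2-week assessment
#' windows, PHQ-8 responses every 14 days, and battery-sampled event logs
#' whose behavioral streams carry the configured depressed-window
#' effects. Each participant has an independent RNG stream derived from
#' the master seed, so output is reproducible and independent of
#' iteration order.
#'
#' @param config A [synth_config()].
#' @return An object of class `sensing_study`: a list with tibbles
#'   `profiles`, `events`, `schedule`, `responses`, `truth_windows`,
#'   `truth_days`, and the `config`.
#' @export
#' @examples
#' study <- simulate_study(synth_config(n_participants = 4, seed = 11))
#' study
simulate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  profiles <- generate_population(config)
  n <- nrow(profiles)
  ev_list <- vector("list", n)
  sch_list <- vector("list", n)
  td_list <- vector("list", n)
  resp_list <- vector("list", n)
  tw_list <- vector("list", n)
  sigma_b <- sqrt(config$icc)
  sigma_w <- sqrt(1 - config$icc)
  rho <- config$ar1_rho

  for (i in seq_len(n)) {
    prof <- profiles[i, ]
    part <- with_seed(derive_seed(config$seed, i), {
      n_days <- draw_followup_days(1L, config)
      start_date <- as.Date("2018-03-01") + sample.int(120L, 1L) - 1L
      resp_offsets <- if (n_days >= 14L) seq(14L, n_days, by = 14L) else n_days
      k <- length(resp_offsets)
      w <- numeric(k)
      w[1] <- rnorm(1L, 0, sigma_w)
      if (k > 1L) {
        for (t in 2:k) w[t] <- rho * w[t - 1L] + rnorm(1L, 0, sigma_w * sqrt(1 - rho^2))
      }
      latent <- rnorm(1L, 0, sigma_b) + w
      resp_dates <- start_date + resp_offsets - 1L
      responses <- dplyr::bind_rows(lapply(seq_len(k), function(t) {
        simulate_phq8(prof, latent[t], resp_dates[t], config)
      }))
      lab <- as.integer(responses$phq8_total >= 10L)
      windows <- tibble(
        start = resp_dates - 13L, end = resp_dates,
        net_mode = sample(c("regular", "erratic"), k, replace = TRUE)
      )[lab == 1L, , drop = FALSE]
      list(
        n_days = n_days, start_date = start_date,
        responses = responses, latent = latent, label = lab,
        windows = windows, resp_dates = resp_dates
      )
    })
    ev <- simulate_participant_days(
      prof, config,
      depressed_windows = part$windows,
      n_days = part$n_days, start_date = part$start_date
    )
    ev_list[[i]] <- ev
    sch_list[[i]] <- attr(ev, "schedule")
    td_list[[i]] <- attr(ev, "truth")
    resp_list[[i]] <- part$responses
    tw_list[[i]] <- tibble(
      participant_id = prof$participant_id,
      response_date = part$resp_dates,
      latent_severity = part$latent,
      true_label = part$label
    )
  }

  structure(
    list(
      profiles = profiles,
      events = dplyr::bind_rows(ev_list),
      schedule = dplyr::bind_rows(sch_list),
      responses = dplyr::bind_rows(resp_list),
      truth_windows = dplyr::bind_rows(tw_list),
      truth_days = dplyr::bind_rows(td_list),
      config = config
    ),
    class = "sensing_study"
  )
}

#' @export
print.sensing_study <- function(x, ...) {
  cat("<sensing_study>\n")
  cat(sprintf(
    "  %d participants, %d event records, %d scheduled days, %d PHQ-8 responses\n",
    nrow(x$profiles), nrow(x$events), nrow(x$schedule), nrow(x$responses)
  ))
  cat(sprintf(
    "  depressed responses: %d (%.1f%%)\n",
    sum(x$truth_windows$true_label),
    100 * mean(x$truth_windows$true_label)
  ))
  invisible(x)
}

#' Write a simulated study to plain-text files
#'
#' Event logs go to `events.csv` (ISO-8601 UTC timestamps), profiles,
#' PHQ-8 responses and the sampling schedule to their own CSVs, and the
#' generator configuration to `config.yaml`.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "sensing_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  events <- study$events
  events$timestamp_utc <- format(events$timestamp_utc, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(events, file.path(dir, "events.csv"))
  readr::write_csv(study$profiles, file.path(dir, "profiles.csv"))
  readr::write_csv(study$responses, file.path(dir, "responses.csv"))
  readr::write_csv(study$schedule, file.path(dir, "schedule.csv"))
  write_synth_config(study$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a study written by [write_study_csv()]
#'
#' @param dir Directory containing the CSV/YAML files.
#' @return A `sensing_study` (without generative truth tables).
#' @export
read_study_csv <- function(dir) {
  events <- readr::read_csv(file.path(dir, "events.csv"),
    col_types = readr::cols(
      participant_id = "c", timestamp_utc = "T", stream = "c",
      value = "c", battery_level = "i"
    )
  )
  structure(
    list(
      profiles = readr::read_csv(file.path(dir, "profiles.csv"), col_types = readr::cols()),
      events = events,
      schedule = readr::read_csv(file.path(dir, "schedule.csv"),
        col_types = readr::cols(local_date = "D", .default = "?")
      ),
      responses = readr::read_csv(file.path(dir, "responses.csv"),
        col_types = readr::cols(response_date = "D", .default = "?")
      ),
      config = read_synth_config(file.path(dir, "config.yaml"))
    ),
    class = "sensing_study"
  )
}
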