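# Day-level behavioral stream simulation.
#
# Screen: alternating on/off dwell sequence whose realized on-duration
# share equals an entropy-targeted value exactly (dwell totals are
# rescaled), so the day's duration-based normalized entropy is controlled
# to numerical precision. Internet: participant hourly connectivity
# template with per-day flip noise (controls the hourly-modal regularity
# index directly). Apps: Poisson launches with Zipf-distributed app choice.

# Invert normalized two-state entropy e = H(p)/ln 2 on the branch
# p in (0, 0.5]. Monotone spline over a fixed grid; ~1e-6 accurate.
.invert_norm_entropy <- local({
  grid_p <- NULL
  grid_e <- NULL
  function(e) {
    if (is.null(grid_p)) {
      p <- seq(1e-6, 0.5, length.out = 4096)
      h <- -(p * log(p) + (1 - p) * log1p(-p)) / log(2)
      grid_p <<- p
      grid_e <<- h
    }
    e <- pmin(pmax(e, 1e-6), 1)
    stats::approx(grid_e, grid_p, xout = e, rule = 2)$y
  }
})

# One day of screen activity: alternating off/on segments over 1440
# minutes, with exactly `p_on` of the day in the "on" state.
# Returns segment start minutes and states; day starts "off".
.screen_day_segments <- function(p_on, mean_on_segments) {
  n_on <- max(1L, rpois(1L, mean_on_segments))
  on_d <- rgamma(n_on, shape = 1.5)
  off_d <- rgamma(n_on + 1L, shape = 1.5)
  on_d <- on_d / sum(on_d) * p_on * 1440
  off_d <- off_d / sum(off_d) * (1 - p_on) * 1440
  dur <- numeric(2L * n_on + 1L)
  dur[seq(1L, 2L * n_on + 1L, by = 2L)] <- off_d
  dur[seq(2L, 2L * n_on, by = 2L)] <- on_d
  starts <- cumsum(c(0, dur[-length(dur)]))
  states <- rep_len(c("off", "on"), length(dur))
  list(start = starts, state = states)
}

# Participant hourly internet-connectivity template: connected except for
# a contiguous nightly offline block wrapping around midnight.
.net_template <- function(offline_hours) {
  len <- max(0L, min(20L, rpois(1L, offline_hours)))
  start <- sample(c(22L, 23L, 0L, 1L, 2L), 1L)
  hours <- if (len == 0L) integer(0) else (start + seq_len(len) - 1L) %% 24L
  conn <- rep(TRUE, 24L)
  conn[hours + 1L] <- FALSE
  conn
}

.pid_index <- function(participant_id) {
  idx <- suppressWarnings(as.integer(gsub("\\D", "", participant_id)))
  if (is.na(idx)) idx <- sum(utf8ToInt(participant_id) * seq_len(nchar(participant_id)))
  idx
}

#' Simulate one participant's smartphone event log
#'
#' Generates battery-change-scheduled event records for a single
#' participant over `n_days` consecutive local days: screen on/off state
#' changes, internet connectivity changes, and foreground app launches.
#' Logging is sampled: a Poisson number of battery-change events is
#' scheduled each day, a fraction `missing_interval_rate` of them emit no
#' log (these are the "missing log intervals" counted by the day filter),
#' and state changes are observed only at retained sampling events. Days
#' falling inside `depressed_windows` receive the configured
#' depressed-state perturbations (screen entropy shift; optionally a
#' bimodal internet-regularity mode).
#'
#' @param profile One-row tibble as returned by [generate_population()].
#' @param config A [synth_config()].
#' @param depressed_windows `NULL`, or a tibble with `start`, `end`
#'   (`Date`) and optionally `net_mode` (`"regular"`/`"erratic"`) per
#'   depressed assessment window.
#' @param n_days Number of follow-up days; `NULL` draws it from the
#'   configured follow-up distribution.
#' @param start_date First local calendar date of follow-up.
#' @return A tibble of event records (`participant_id`, `timestamp_utc`,
#'   `stream`, `value`, `battery_level`), sorted by time, with attributes
#'   `schedule` (per-day scheduled/missing sampling-event counts) and
#'   `truth` (per-day generative targets, for diagnostics).
#' @export
#' @examples
#' cfg <- synth_config(n_participants = 1, seed = 3)
#' prof <- generate_population(cfg)
#' ev <- simulate_participant_days(prof[1, ], cfg, n_days = 8)
#' head(ev)
simulate_participant_days <- function(profile, config, depressed_windows = NULL,
                                      n_days = NULL,
                                      start_date = as.Date("2018-03-01")) {
  stopifnot(inherits(config, "synth_config"), nrow(profile) == 1L)
  pid <- profile$participant_id
  seed <- derive_seed(config$seed, 1000000L + .pid_index(pid))
  with_seed(seed, {
    if (is.null(n_days)) n_days <- draw_followup_days(1L, config)
    n_days <- as.integer(n_days)
    if (n_days < config$days_range[1] || n_days > config$days_range[2]) {
      stop_config("`n_days` = %d outside configured days_range", n_days)
    }
    dates <- start_date + seq_len(n_days) - 1L

    depressed <- rep(FALSE, n_days)
    net_mode <- rep("baseline", n_days)
    if (!is.null(depressed_windows) && nrow(depressed_windows) > 0L) {
      for (w in seq_len(nrow(depressed_windows))) {
        inw <- dates >= depressed_windows$start[w] & dates <= depressed_windows$end[w]
        depressed[inw] <- TRUE
        if (config$nonlinear_effect_flag) {
          mode <- if ("net_mode" %in% names(depressed_windows)) {
            depressed_windows$net_mode[w]
          } else {
            sample(c("regular", "erratic"), 1L)
          }
          net_mode[inw] <- mode
        }
      }
    }

    # --- screen: entropy-targeted dwell model -------------------------
    sigma_e <- sqrt(config$entropy_between_sd^2 + config$entropy_within_sd^2)
    eta_i <- rnorm(1L, 0, config$entropy_between_sd)
    e_day <- config$entropy_base_mean + eta_i +
      rnorm(n_days, 0, config$entropy_within_sd) +
      config$entropy_effect * sigma_e * depressed
    e_day <- pmin(pmax(e_day, 0.02), 0.995)
    p_on <- .invert_norm_entropy(e_day)
    seg <- lapply(seq_len(n_days), function(d) {
      s <- .screen_day_segments(p_on[d], config$screen_switch_rate)
      s$start <- s$start + (d - 1L) * 1440
      s
    })
    scr_start <- unlist(lapply(seg, `[[`, "start"))
    scr_state <- unlist(lapply(seg, `[[`, "state"))

    # --- internet: hourly template with per-day flip noise ------------
    template <- .net_template(config$net_offline_hours)
    # The two depressed modes are symmetric around the baseline flip rate,
    # so the injected internet-regularity structure is non-monotone
    # (bimodal) without adding a linear association with the label.
    flip_rate <- dplyr::case_match(net_mode,
      "regular" ~ config$net_flip_rate - 0.16,
      "erratic" ~ config$net_flip_rate + 0.16,
      .default = config$net_flip_rate
    )
    hourly_conn <- matrix(rep(template, n_days), nrow = 24L)
    flips <- matrix(runif(24L * n_days) < rep(flip_rate, each = 24L), nrow = 24L)
    hourly_conn <- xor(hourly_conn, flips)
    net_state_hr <- ifelse(as.vector(hourly_conn), "connected", "disconnected")
    net_start_hr <- (seq_along(net_state_hr) - 1L) * 60

    # --- apps: Poisson launches, Zipf app choice ----------------------
    lambda_i <- rgamma(1L, shape = 4, rate = 4 / config$app_rate)
    n_app_day <- rpois(n_days, lambda_i)
    n_app <- sum(n_app_day)
    app_minute <- unlist(lapply(seq_len(n_days), function(d) {
      if (n_app_day[d] == 0L) return(numeric(0))
      sort(runif(n_app_day[d], 420, 1410)) + (d - 1L) * 1440
    }))
    zipf_w <- 1 / seq_len(config$app_catalog_size)
    app_id <- if (n_app > 0L) {
      paste0("app_", sample.int(config$app_catalog_size, n_app,
        replace = TRUE, prob = zipf_w
      ))
    } else {
      character(0)
    }

    # --- battery-change sampling schedule -----------------------------
    n_sched_day <- rpois(n_days, config$battery_events_per_day)
    sched_minute <- unlist(lapply(seq_len(n_days), function(d) {
      sort(runif(n_sched_day[d], 0, 1440)) + (d - 1L) * 1440
    }))
    n_sched <- length(sched_minute)
    missing <- runif(n_sched) < config$missing_interval_rate
    battery <- pmin(pmax(round(cumsum(rnorm(n_sched, 0, 1.2)) + runif(1, 30, 90)), 1), 100)

    kept <- which(!missing)
    kept_minute <- sched_minute[kept]

    # observed states at retained sampling events; emit on change only
    emit_changes <- function(minutes, state_at) {
      st <- state_at(minutes)
      keep <- c(TRUE, st[-1L] != st[-length(st)])
      list(minute = minutes[keep], value = st[keep], battery = battery[kept][keep])
    }
    scr_obs <- if (length(kept_minute) > 0L) {
      emit_changes(kept_minute, function(m) scr_state[findInterval(m, scr_start)])
    } else {
      list(minute = numeric(0), value = character(0), battery = integer(0))
    }
    net_obs <- if (length(kept_minute) > 0L) {
      emit_changes(kept_minute, function(m) {
        net_state_hr[pmin(length(net_state_hr), m %/% 60 + 1L)]
      })
    } else {
      list(minute = numeric(0), value = character(0), battery = integer(0))
    }

    # app launches survive only if their covering sampling event logged
    if (n_app > 0L && n_sched > 0L) {
      cover <- findInterval(app_minute, sched_minute, left.open = TRUE) + 1L
      ok <- cover <= n_sched & !missing[pmin(cover, n_sched)]
      app_minute <- app_minute[ok]
      app_id <- app_id[ok]
      app_batt <- battery[pmin(cover[ok], n_sched)]
    } else {
      app_minute <- numeric(0)
      app_id <- character(0)
      app_batt <- integer(0)
    }

    local_midnight <- as.POSIXct(paste(start_date, "00:00:00"), tz = profile$timezone)
    to_utc <- function(minutes) {
      lubridate::with_tz(local_midnight + minutes * 60, "UTC")
    }
    events <- dplyr::bind_rows(
      tibble(
        minute = scr_obs$minute, stream = "screen",
        value = scr_obs$value, battery_level = scr_obs$battery
      ),
      tibble(
        minute = net_obs$minute, stream = "internet",
        value = net_obs$value, battery_level = net_obs$battery
      ),
      tibble(
        minute = app_minute, stream = "app",
        value = app_id, battery_level = app_batt
      )
    )
    events <- events[order(events$minute), , drop = FALSE]
    events <- tibble(
      participant_id = pid,
      timestamp_utc = to_utc(events$minute),
      stream = events$stream,
      value = events$value,
      battery_level = as.integer(events$battery_level)
    )

    miss_day <- tabulate(findInterval(sched_minute[missing], (seq_len(n_days) - 1L) * 1440),
      nbins = n_days
    )
    attr(events, "schedule") <- tibble(
      participant_id = pid, local_date = dates,
      scheduled = n_sched_day, missing_intervals = as.integer(miss_day)
    )
    attr(events, "truth") <- tibble(
      participant_id = pid, local_date = dates,
      target_norm_entropy = e_day, target_p_on = p_on,
      depressed_day = depressed, net_mode = net_mode
    )
    events
  })
}

#' Draw follow-up lengths from the configured cohort distribution
#'
#' Follow-up days per participant are `min_days + X` with `X` negative
#' binomial, moment-matched to a mean of 22.1 and SD of 17.9 days and
#' truncated to the configured range — a right-skewed distribution in
#' which roughly half the cohort contributes only 8-14 days.
#'
#' @param n Number of draws.
#' @param config A [synth_config()].
#' @return Integer vector of day counts within `config$days_range`.
#' @export
draw_followup_days <- function(n, config) {
  lo <- config$days_range[1]
  hi <- config$days_range[2]
  mu <- max(22.1 - lo, 0.5)
  v <- 17.9^2
  size <- if (v > mu) mu^2 / (v - mu) else 100
  x <- lo + stats::rnbinom(n, size = size, mu = mu)
  pmin(pmax(x, lo), hi)
}
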