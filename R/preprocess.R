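# Localize UTC event logs to participant time, segment into days, and
# apply the day- and response-level inclusion filters.

# Map events to a participant-local "minute axis": minutes since the
# participant's local midnight of an arbitrary epoch. Duration accounting
# is done on this local-clock axis.
.local_minutes <- function(ts_utc, tz) {
  local <- lubridate::with_tz(ts_utc, tz)
  date <- as.Date(local, tz = tz)
  mins <- as.numeric(difftime(
    local,
    as.POSIXct(paste(date, "00:00:00"), tz = tz),
    units = "mins"
  ))
  list(date = date, minute = pmin(pmax(mins, 0), 1439.999))
}

# Carry-forward state intervals for one participant/stream on the
# absolute local-minute axis. Days before the first log start in
# `default_state`.
.state_intervals <- function(abs_min, value, axis_start, axis_end, default_state) {
  if (length(abs_min) == 0L) {
    return(tibble(start = axis_start, end = axis_end, state = default_state))
  }
  starts <- c(axis_start, abs_min)
  states <- c(default_state, value)
  ends <- c(abs_min, axis_end)
  keep <- ends > starts
  tibble(start = starts[keep], end = ends[keep], state = states[keep])
}

# Overlap minutes of intervals with unit bins of width `width` (1440 for
# days, 60 for hours). Returns bin index (0-based) and minutes.
.bin_overlap <- function(start, end, width) {
  b0 <- floor(start / width)
  b1 <- floor((end - 1e-9) / width)
  n <- b1 - b0 + 1L
  idx <- rep(seq_along(start), n)
  bin <- b0[idx] + sequence(n) - 1
  s <- pmax(start[idx], bin * width)
  e <- pmin(end[idx], (bin + 1) * width)
  tibble(interval = idx, bin = bin, minutes = e - s)
}

# Per-day minutes in the "positive" state plus 24 hourly positive-minute
# vectors, for one participant/stream.
.daily_state_minutes <- function(intervals, positive) {
  pos <- intervals[intervals$state == positive, , drop = FALSE]
  if (nrow(pos) == 0L) {
    return(list(
      day = tibble(day = numeric(0), pos_minutes = numeric(0)),
      hour = tibble(day = numeric(0), hour = integer(0), pos_minutes = numeric(0))
    ))
  }
  dd <- .bin_overlap(pos$start, pos$end, 1440)
  day <- dplyr::summarise(dplyr::group_by(dd, day = .data$bin),
    pos_minutes = sum(.data$minutes), .groups = "drop"
  )
  hh <- .bin_overlap(pos$start, pos$end, 60)
  hour <- dplyr::summarise(
    dplyr::group_by(hh, day = .data$bin %/% 24, hour = as.integer(.data$bin %% 24)),
    pos_minutes = sum(.data$minutes), .groups = "drop"
  )
  list(day = day, hour = hour)
}

#' Localize event logs and build per-day summaries
#'
#' Converts UTC timestamps to each participant's local time, assigns
#' every event to exactly one local calendar day, and summarizes each
#' day: per-state durations and hourly modal states for screen and
#' internet (carry-forward between logs, hours with no information
#' inherit the last known state, a day with no prior state starts
#' off/disconnected; modal ties break toward off/disconnected), hourly
#' distinct-app counts, per-epoch and per-day event counts, first/last
#' app-use minutes, and the day's count of missing log intervals.
#'
#' @param events Event tibble (`participant_id`, `timestamp_utc`,
#'   `stream`, `value`, `battery_level`).
#' @param profiles Participant profiles with `participant_id`, `timezone`.
#' @param schedule Optional per-day sampling schedule
#'   (`participant_id`, `local_date`, `missing_intervals`) as produced by
#'   the generator. If `NULL`, missing intervals are inferred from log
#'   gaps via [infer_missing_intervals()].
#' @return A day-summary tibble, one row per participant-day with at
#'   least one event. Hourly vectors are list-columns of length 24;
#'   `app_freqs` is a list-column of named per-app launch counts.
#' @export
localize_and_segment <- function(events, profiles, schedule = NULL) {
  if (nrow(events) == 0L) {
    return(.empty_day_summary())
  }
  miss <- setdiff(unique(events$participant_id), profiles$participant_id)
  if (length(miss) > 0L) {
    stop_config("events reference participants without profiles: %s", miss[1])
  }
  bad_tz <- setdiff(unique(profiles$timezone), OlsonNames())
  if (length(bad_tz) > 0L) {
    stop_config("unknown timezone `%s`", bad_tz[1])
  }
  ev <- dplyr::inner_join(events, profiles[, c("participant_id", "timezone")],
    by = "participant_id"
  )
  ev <- dplyr::arrange(ev, .data$participant_id, .data$timestamp_utc)

  out <- lapply(split(ev, ev$participant_id), function(pe) {
    tz <- pe$timezone[1]
    loc <- .local_minutes(pe$timestamp_utc, tz)
    pe$local_date <- loc$date
    day0 <- min(pe$local_date)
    pe$abs_min <- as.numeric(pe$local_date - day0) * 1440 + loc$minute
    axis_start <- 0
    axis_end <- (as.numeric(max(pe$local_date) - day0) + 1) * 1440
    day_index <- sort(unique(as.numeric(pe$local_date - day0)))
    dates <- day0 + day_index

    summary <- tibble(
      participant_id = pe$participant_id[1],
      local_date = dates
    )
    summary$.day <- day_index

    for (spec in list(
      list(stream = "screen", positive = "on", default = "off", col = "screen"),
      list(stream = "internet", positive = "connected", default = "disconnected", col = "net")
    )) {
      se <- pe[pe$stream == spec$stream, , drop = FALSE]
      iv <- .state_intervals(se$abs_min, se$value, axis_start, axis_end, spec$default)
      mins <- .daily_state_minutes(iv, spec$positive)
      pos_day <- mins$day$pos_minutes[match(day_index, mins$day$day)]
      pos_day[is.na(pos_day)] <- 0
      summary[[paste0(spec$col, "_pos_minutes")]] <- pos_day
      hr <- matrix(0, nrow = length(day_index), ncol = 24L)
      if (nrow(mins$hour) > 0L) {
        ri <- match(mins$hour$day, day_index)
        ok <- !is.na(ri)
        hr[cbind(ri[ok], mins$hour$hour[ok] + 1L)] <- mins$hour$pos_minutes[ok]
      }
      states <- ifelse(hr > 30, spec$positive, spec$default)
      summary[[paste0("hourly_", spec$col)]] <- lapply(
        seq_len(nrow(states)), function(r) states[r, ]
      )
    }

    # event counts per day and epoch -----------------------------------
    pe$hour <- as.integer(pe$abs_min %% 1440) %/% 60L
    pe$type <- dplyr::case_when(
      pe$stream == "screen" & pe$value == "on" ~ "screen_on",
      pe$stream == "screen" ~ "screen_off",
      pe$stream == "internet" & pe$value == "connected" ~ "net_connected",
      pe$stream == "internet" ~ "net_disconnected",
      TRUE ~ "app_use"
    )
    pe$epoch <- .epoch_of_hour(pe$hour)
    pe$.day <- as.numeric(pe$local_date - day0)
    types <- c("screen_on", "screen_off", "net_connected", "net_disconnected", "app_use")
    for (ty in types) {
      for (epo in .epoch_levels) {
        cnt <- tapply(
          pe$type == ty & pe$epoch == epo, pe$.day, sum
        )[as.character(day_index)]
        summary[[paste0("epoch_", ty, "_", epo)]] <- as.integer(ifelse(is.na(cnt), 0L, cnt))
      }
      cnt <- tapply(pe$type == ty, pe$.day, sum)[as.character(day_index)]
      summary[[paste0("count_", ty)]] <- as.integer(ifelse(is.na(cnt), 0L, cnt))
    }

    # app details -------------------------------------------------------
    ap <- pe[pe$stream == "app", , drop = FALSE]
    ap_by_day <- split(ap, factor(ap$.day, levels = day_index))
    summary$app_distinct_count <- unname(vapply(
      ap_by_day, function(d) length(unique(d$value)), integer(1)
    ))
    summary$app_first_minute <- unname(vapply(ap_by_day, function(d) {
      if (nrow(d) == 0L) NA_real_ else min(d$abs_min %% 1440)
    }, numeric(1)))
    summary$app_last_minute <- unname(vapply(ap_by_day, function(d) {
      if (nrow(d) == 0L) NA_real_ else max(d$abs_min %% 1440)
    }, numeric(1)))
    summary$hourly_app_distinct <- lapply(ap_by_day, function(d) {
      out <- integer(24L)
      if (nrow(d) > 0L) {
        tab <- tapply(d$value, d$hour, function(v) length(unique(v)))
        out[as.integer(names(tab)) + 1L] <- as.integer(tab)
      }
      out
    })
    summary$app_freqs <- lapply(ap_by_day, function(d) {
      if (nrow(d) == 0L) integer(0) else table(d$value)
    })
    summary$.day <- NULL
    summary
  })
  days <- dplyr::bind_rows(out)
  rownames(days) <- NULL

  if (!is.null(schedule)) {
    days <- dplyr::left_join(
      days, schedule[, c("participant_id", "local_date", "missing_intervals")],
      by = c("participant_id", "local_date")
    )
    days$missing_intervals[is.na(days$missing_intervals)] <- 0L
  } else {
    days <- dplyr::left_join(days, infer_missing_intervals(events, profiles),
      by = c("participant_id", "local_date")
    )
    days$missing_intervals[is.na(days$missing_intervals)] <- 0L
  }
  days
}

.empty_day_summary <- function() {
  tibble(
    participant_id = character(0), local_date = as.Date(character(0)),
    missing_intervals = integer(0)
  )
}

#' Infer missing log intervals from gaps between logs
#'
#' For real logs without an explicit sampling schedule, a missing log
#' interval is inferred wherever the gap between consecutive logs of a
#' participant-day exceeds twice that participant-day's median gap; each
#' such gap contributes `round(gap / median) - 1` missing intervals.
#'
#' @inheritParams localize_and_segment
#' @return Tibble `participant_id`, `local_date`, `missing_intervals`.
#' @export
infer_missing_intervals <- function(events, profiles) {
  ev <- dplyr::inner_join(events, profiles[, c("participant_id", "timezone")],
    by = "participant_id"
  )
  ev <- dplyr::arrange(ev, .data$participant_id, .data$timestamp_utc)
  parts <- split(ev, ev$participant_id)
  dplyr::bind_rows(lapply(parts, function(pe) {
    loc <- .local_minutes(pe$timestamp_utc, pe$timezone[1])
    tibble(local_date = loc$date, minute = loc$minute) |>
      dplyr::group_by(.data$local_date) |>
      dplyr::summarise(
        missing_intervals = {
          gaps <- diff(sort(.data$minute))
          med <- stats::median(gaps)
          if (length(gaps) < 2L || !is.finite(med) || med <= 0) {
            0L
          } else {
            long <- gaps[gaps > 2 * med]
            as.integer(sum(pmax(round(long / med) - 1, 1)))
          }
        },
        .groups = "drop"
      ) |>
      dplyr::mutate(participant_id = pe$participant_id[1], .before = 1)
  }))
}

#' Day-level inclusion filter
#'
#' Retains exactly the participant-days with fewer than 10 missing log
#' intervals.
#'
#' @param days Day-summary tibble from [localize_and_segment()].
#' @return The filtered tibble.
#' @export
filter_days <- function(days) {
  stopifnot("missing_intervals" %in% names(days))
  days[days$missing_intervals < 10L, , drop = FALSE]
}

#' Response-level inclusion filter
#'
#' Retains PHQ-8 responses whose 14-day assessment window (the 14
#' calendar days ending on the response date, inclusive) contains at
#' least 8 retained days for that participant.
#'
#' @param responses PHQ-8 response tibble (`participant_id`,
#'   `response_date`).
#' @param days Day-summary tibble already passed through [filter_days()].
#' @param window_days Assessment-window length in days (default 14).
#' @param min_days Minimum retained days required (default 8).
#' @param include_response_day Whether the window includes the response
#'   date itself (default `TRUE`).
#' @return The filtered response tibble.
#' @export
filter_responses <- function(responses, days, window_days = 14L, min_days = 8L,
                             include_response_day = TRUE) {
  if (nrow(responses) == 0L) return(responses)
  n_in_window <- vapply(seq_len(nrow(responses)), function(i) {
    d <- days[days$participant_id == responses$participant_id[i], , drop = FALSE]
    end <- responses$response_date[i] - if (include_response_day) 0L else 1L
    start <- end - window_days + 1L
    sum(d$local_date >= start & d$local_date <= end)
  }, numeric(1))
  responses[n_in_window >= min_days, , drop = FALSE]
}
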