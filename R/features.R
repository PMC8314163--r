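# The 22 day-level behavioral markers.

#' Canonical day-level feature names
#'
#' The 22 behavioral markers: 6 counts, 6 entropies (raw and normalized
#' for screen, internet, app), 3 regularity indices, 5 epoch-count SDs,
#' and first/last app-use minutes.
#'
#' @return Character vector of length 22.
#' @export
feature_names <- function() {
  c(
    "screen_onCount", "screen_offCount", "net_connectedCount",
    "net_disconnectedCount", "app_count", "app_distinctCount",
    "screen_entropy", "screen_normEntropy", "net_entropy",
    "net_normEntropy", "app_entropy", "app_normEntropy",
    "screen_regIndex", "net_regIndex", "app_regIndex",
    "screen_onCountSD", "screen_offCountSD", "net_connectedCountSD",
    "net_disconnectedCountSD", "app_countSD",
    "app_firstUseMinutes", "app_lastUseMinutes"
  )
}

# Feature groups used by pooling (mean vs pooled-SD aggregation).
.sd_features <- c(
  "screen_onCountSD", "screen_offCountSD", "net_connectedCountSD",
  "net_disconnectedCountSD", "app_countSD"
)

#' Shannon entropy of a state distribution
#'
#' `H = -sum(p_i * log(p_i))` in nats, with `0 * log(0)` taken as 0.
#'
#' @param p Probability vector (non-negative, summing to 1 within 1e-9).
#' @return Entropy in nats (>= 0).
#' @export
#' @examples
#' shannon_entropy(c(0.25, 0.75))
shannon_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_config("proportions must be non-negative and finite")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_config("proportions must sum to 1 (got %.12f)", sum(p))
  }
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

#' Normalized Shannon entropy
#'
#' Entropy divided by `log(N)` where `N` is the number of declared
#' states, bounded in `[0, 1]`. A single-state distribution (N = 1, or
#' all mass on one state) is defined to have normalized entropy 0.
#'
#' @inheritParams shannon_entropy
#' @return Dimensionless value in `[0, 1]`.
#' @export
#' @examples
#' normalized_entropy(c(0.25, 0.75))
normalized_entropy <- function(p) {
  h <- shannon_entropy(p)
  n <- length(p)
  if (n < 2L || h == 0) return(0)
  h / log(n)
}

#' Regularity index of a pair of days
#'
#' Hour-by-hour similarity of two days:
#' `R(a, b) = mean(x_a(t) * x_b(t))` over the 24 hours, where the hourly
#' values have been rescaled to `[-0.5, 0.5]`. The index lies in
#' `[-0.25, 0.25]`; identical extreme days score 0.25 and opposite
#' extreme days score -0.25.
#'
#' @param a,b Numeric vectors of length 24 with values in `[-0.5, 0.5]`
#'   (use [rescale_binary_hours()] or [rescale_count_pair()]).
#' @return Dimensionless value in `[-0.25, 0.25]`.
#' @export
#' @examples
#' regularity_index_pair(rep(0.5, 24), rep(-0.5, 24))
regularity_index_pair <- function(a, b) {
  if (length(a) != 24L || length(b) != 24L) {
    stop_config("hourly vectors must have length 24")
  }
  if (any(abs(a) > 0.5 + 1e-12) || any(abs(b) > 0.5 + 1e-12)) {
    stop_config("hourly values must be rescaled into [-0.5, 0.5]")
  }
  mean(a * b)
}

#' Rescale hourly modal states to `[-0.5, 0.5]`
#'
#' Binary hourly states map to +0.5 (the active state: on/connected) and
#' -0.5 (off/disconnected).
#'
#' @param states Character vector of length 24.
#' @param positive The state mapped to +0.5.
#' @return Numeric vector of length 24.
#' @export
rescale_binary_hours <- function(states, positive) {
  ifelse(states == positive, 0.5, -0.5)
}

#' Rescale a pair of hourly count vectors to `[-0.5, 0.5]`
#'
#' Linear map of both days' hourly counts from `[0, max]` to
#' `[-0.5, 0.5]`, where `max` is taken over the day pair. A pair whose
#' maximum is 0 is flagged so the pair's regularity is defined as 0.
#'
#' @param a,b Non-negative numeric vectors of length 24.
#' @return List with rescaled `a`, `b`, and `degenerate` (logical).
#' @export
rescale_count_pair <- function(a, b) {
  m <- max(a, b)
  if (m == 0) {
    return(list(a = rep(0, 24L), b = rep(0, 24L), degenerate = TRUE))
  }
  list(a = a / m - 0.5, b = b / m - 0.5, degenerate = FALSE)
}

#' Average regularity of a day against its week peers
#'
#' The regularity feature of a day is the mean [regularity_index_pair()]
#' between that day and every other retained day in the same ISO-8601
#' week. A day with no peers has a missing regularity feature.
#'
#' @param target_day One-row day summary.
#' @param peer_days Day summaries of the other days in the same week.
#' @param stream One of `"screen"`, `"net"`, `"app"`.
#' @return Scalar regularity, or `NA` if there are no peers.
#' @export
daily_regularity <- function(target_day, peer_days, stream = c("screen", "net", "app")) {
  stream <- match.arg(stream)
  if (nrow(peer_days) == 0L) return(NA_real_)
  get_hours <- function(row) {
    switch(stream,
      screen = row$hourly_screen[[1]],
      net = row$hourly_net[[1]],
      app = row$hourly_app_distinct[[1]]
    )
  }
  ta <- get_hours(target_day)
  scores <- vapply(seq_len(nrow(peer_days)), function(j) {
    tb <- get_hours(peer_days[j, ])
    if (stream == "app") {
      rs <- rescale_count_pair(ta, tb)
      if (rs$degenerate) 0 else regularity_index_pair(rs$a, rs$b)
    } else {
      pos <- if (stream == "screen") "on" else "connected"
      regularity_index_pair(
        rescale_binary_hours(ta, pos), rescale_binary_hours(tb, pos)
      )
    }
  }, numeric(1))
  mean(scores)
}

#' Sample SD of the four epoch counts of a day
#'
#' The SD (denominator n - 1 = 3) of an event type's counts over the
#' night/morning/afternoon/evening epochs.
#'
#' @param counts Numeric vector of exactly 4 epoch counts.
#' @return Non-negative scalar.
#' @export
#' @examples
#' epoch_count_sd(c(0, 0, 0, 12))
epoch_count_sd <- function(counts) {
  if (length(counts) != 4L) stop_config("exactly 4 epoch counts required")
  sd(counts)
}

# Vectorized two-state entropy from a positive-state proportion.
.binary_entropy <- function(p) {
  q <- 1 - p
  h <- numeric(length(p))
  nz <- p > 0 & p < 1
  h[nz] <- -(p[nz] * log(p[nz]) + q[nz] * log(q[nz]))
  h
}

#' Compute the 22 day-level features
#'
#' Turns filtered day summaries into the canonical day-level feature
#' table. Entropies use state-duration proportions for screen and
#' internet (carry-forward durations) and per-app launch-frequency
#' proportions for apps; regularity indices average over same-ISO-week
#' peer days; epoch SDs are per-day sample SDs over the four day epochs.
#' Regularity is missing for days with no week peers, and app-use-time
#' features are missing for days with no app events.
#'
#' @param days Day-summary tibble from [localize_and_segment()]
#'   (normally after [filter_days()]).
#' @return Tibble with `participant_id`, `local_date` and the 22 columns
#'   of [feature_names()].
#' @export
extract_features <- function(days) {
  if (nrow(days) == 0L) {
    out <- tibble(participant_id = character(0), local_date = as.Date(character(0)))
    out[feature_names()] <- lapply(feature_names(), function(x) numeric(0))
    return(out)
  }
  p_scr <- days$screen_pos_minutes / 1440
  p_net <- days$net_pos_minutes / 1440
  n_scr_states <- (p_scr > 0) + (p_scr < 1)
  n_net_states <- (p_net > 0) + (p_net < 1)
  app_h <- vapply(days$app_freqs, function(f) {
    if (length(f) == 0L || sum(f) == 0L) 0 else shannon_entropy(as.numeric(f) / sum(f))
  }, numeric(1))
  app_n <- vapply(days$app_freqs, length, integer(1))

  out <- tibble(
    participant_id = days$participant_id,
    local_date = days$local_date,
    screen_onCount = as.numeric(days$count_screen_on),
    screen_offCount = as.numeric(days$count_screen_off),
    net_connectedCount = as.numeric(days$count_net_connected),
    net_disconnectedCount = as.numeric(days$count_net_disconnected),
    app_count = as.numeric(days$count_app_use),
    app_distinctCount = as.numeric(days$app_distinct_count),
    screen_entropy = .binary_entropy(p_scr),
    screen_normEntropy = ifelse(n_scr_states < 2L, 0, .binary_entropy(p_scr) / log(2)),
    net_entropy = .binary_entropy(p_net),
    net_normEntropy = ifelse(n_net_states < 2L, 0, .binary_entropy(p_net) / log(2)),
    app_entropy = app_h,
    app_normEntropy = ifelse(app_n < 2L, 0, app_h / log(pmax(app_n, 2L))),
    app_firstUseMinutes = days$app_first_minute,
    app_lastUseMinutes = days$app_last_minute
  )

  sd_src <- c(
    screen_onCountSD = "screen_on", screen_offCountSD = "screen_off",
    net_connectedCountSD = "net_connected",
    net_disconnectedCountSD = "net_disconnected", app_countSD = "app_use"
  )
  for (ty in names(sd_src)) {
    mat <- as.matrix(days[paste0("epoch_", sd_src[[ty]], "_", .epoch_levels)])
    out[[ty]] <- apply(mat, 1L, sd)
  }

  # regularity: group by participant and ISO week
  iso <- sprintf(
    "%d-W%02d", lubridate::isoyear(days$local_date), lubridate::isoweek(days$local_date)
  )
  key <- paste(days$participant_id, iso)
  reg <- matrix(NA_real_, nrow = nrow(days), ncol = 3L,
    dimnames = list(NULL, c("screen", "net", "app"))
  )
  for (idx in split(seq_len(nrow(days)), key)) {
    if (length(idx) < 2L) next
    for (stream in c("screen", "net", "app")) {
      for (i in idx) {
        reg[i, stream] <- daily_regularity(
          days[i, ], days[setdiff(idx, i), ], stream
        )
      }
    }
  }
  out$screen_regIndex <- reg[, "screen"]
  out$net_regIndex <- reg[, "net"]
  out$app_regIndex <- reg[, "app"]
  out[c("participant_id", "local_date", feature_names())]
}
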