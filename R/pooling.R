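# Window-level pooling of day features onto PHQ-8 responses.

#' Depression label from a PHQ-8 total
#'
#' Label 1 (depressed) iff the total is at least 10; label 0 otherwise.
#'
#' @param total PHQ-8 total score(s) in 0-24.
#' @return Integer vector of 0/1 labels.
#' @export
#' @examples
#' label_phq8(c(0, 9, 10, 24))
label_phq8 <- function(total) {
  if (any(!is.finite(total)) || any(total < 0) || any(total > 24)) {
    stop_config("PHQ-8 totals must lie in [0, 24]")
  }
  as.integer(total >= 10)
}

#' Pool one assessment window
#'
#' Aggregates the day-level features of the 14 calendar days ending on
#' the response date into one analysis row: arithmetic means for count,
#' entropy, regularity and app-use-time features (days with a missing
#' value contribute nothing to that feature's mean), and the pooled SD
#' `sqrt(sum((n_i - 1) s_i^2) / sum(n_i - 1))` for the epoch-SD features,
#' which with `n_i = 4` epochs per day reduces to the square root of the
#' mean daily variance.
#'
#' @param days Day-feature rows (from [extract_features()]) falling in
#'   the response's window.
#' @param response One-row PHQ-8 response (`participant_id`,
#'   `response_date`, `phq8_total`).
#' @return One-row pooled-sample tibble with the 22 features,
#'   `phq8_total`, `label` and `n_days_in_window`.
#' @export
pool_window <- function(days, response) {
  if (nrow(days) < 8L) {
    stop_config(
      "window for %s @ %s has %d days (< 8); responses must pass filter_responses()",
      response$participant_id, format(response$response_date), nrow(days)
    )
  }
  out <- tibble(
    participant_id = response$participant_id,
    response_date = response$response_date
  )
  for (f in feature_names()) {
    x <- days[[f]]
    out[[f]] <- if (f %in% .sd_features) {
      sqrt(mean(x[!is.na(x)]^2))
    } else if (all(is.na(x))) {
      NA_real_
    } else {
      mean(x, na.rm = TRUE)
    }
  }
  out$phq8_total <- response$phq8_total
  out$label <- label_phq8(response$phq8_total)
  out$n_days_in_window <- nrow(days)
  out
}

#' Pool all responses over their assessment windows
#'
#' @param features Day-feature tibble from [extract_features()].
#' @param responses Filtered PHQ-8 responses (see [filter_responses()]).
#' @param window_days,include_response_day Window definition, as in
#'   [filter_responses()].
#' @return Pooled-sample tibble, one row per response.
#' @export
pool_windows <- function(features, responses, window_days = 14L,
                         include_response_day = TRUE) {
  rows <- lapply(seq_len(nrow(responses)), function(i) {
    r <- responses[i, ]
    end <- r$response_date - if (include_response_day) 0L else 1L
    start <- end - window_days + 1L
    d <- features[
      features$participant_id == r$participant_id &
        features$local_date >= start & features$local_date <= end, ,
      drop = FALSE
    ]
    pool_window(d, r)
  })
  dplyr::bind_rows(rows)
}

#' Drop exact-duplicate analysis rows
#'
#' Rows identical on all 22 features and the label are reduced to their
#' first occurrence; order is otherwise preserved.
#'
#' @param samples Pooled-sample tibble.
#' @return The deduplicated tibble.
#' @export
deduplicate_samples <- function(samples) {
  if (nrow(samples) == 0L) return(samples)
  key_cols <- c(intersect(feature_names(), names(samples)), "label")
  samples[!duplicated(samples[key_cols]), , drop = FALSE]
}
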