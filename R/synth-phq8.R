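#' Simulate one PHQ-8 assessment from a latent severity
#'
#' Maps a latent severity (marginally standard normal across the
#' population) through the quantile function of the configured PHQ-8
#' total distribution (see [phq8_total_pmf()]), then allocates the total
#' over the 8 items as a uniform random composition with item scores
#' capped at 3. By construction totals lie in 0-24 and
#' `P(total >= 10)` equals the configured prevalence exactly in the
#' population of latents.
#'
#' @param profile One-row participant profile.
#' @param window_state Latent severity for the assessment window (finite
#'   scalar; standard normal marginally under [simulate_study()]).
#' @param response_date Local calendar date of the response.
#' @param config A [synth_config()].
#' @return One-row tibble: `participant_id`, `response_date`,
#'   `item_1` .. `item_8`, `phq8_total`.
#' @export
#' @examples
#' cfg <- synth_config(n_participants = 1, seed = 1)
#' prof <- generate_population(cfg)
#' set.seed(1)
#' simulate_phq8(prof[1, ], 2.5, as.Date("2018-03-14"), cfg)
simulate_phq8 <- function(profile, window_state, response_date, config) {
  stopifnot(is.finite(window_state))
  pmf <- phq8_total_pmf(config$prevalence, config$phq8_mean, config$phq8_sd)
  total <- phq8_total_from_latent(window_state, pmf)
  items <- allocate_phq8_items(total)
  out <- tibble(
    participant_id = profile$participant_id,
    response_date = as.Date(response_date)
  )
  out[paste0("item_", 1:8)] <- as.list(items)
  out$phq8_total <- total
  out
}

# Quantile transform of standard-normal latents to the discrete total pmf.
phq8_total_from_latent <- function(z, pmf) {
  u <- pnorm(z)
  cum <- cumsum(pmf)
  as.integer(findInterval(u, cum, left.open = TRUE))
}

# Uniform random composition of `total` into 8 parts, each capped at 3.
allocate_phq8_items <- function(total) {
  stopifnot(total >= 0, total <= 24)
  items <- integer(8L)
  for (k in seq_len(total)) {
    room <- which(items < 3L)
    pick <- if (length(room) == 1L) room else sample(room, 1L)
    items[pick] <- items[pick] + 1L
  }
  items
}
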