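#' Demographic marginals of the reference cohort
#'
#' Named probability vectors for the five self-reported demographic
#' variables (age group, gender, education, occupation, country),
#' matching the published summary distribution of a 629-participant
#' crowdsourced Android sensing cohort. Used as the default
#' `demographic_marginals` of [synth_config()].
#'
#' @return A named list of named probability vectors, each summing to 1.
#' @export
#' @examples
#' vapply(default_demographic_marginals(), sum, numeric(1))
default_demographic_marginals <- function() {
  list(
    age_group = c(
      "18-24" = 73, "25-34" = 204, "35-44" = 156, "45-64" = 166,
      ">=65" = 30
    ) / 629,
    gender = c("female" = 69, "male" = 546, "other" = 14) / 629,
    education = c(
      "elementary" = 9, "high_school" = 98, "none_or_undisclosed" = 5,
      "professional_graduate" = 193, "research_graduate" = 34,
      "undergraduate" = 228, "vocational" = 62
    ) / 629,
    occupation = c(
      "agriculture_forestry_fishery" = 1, "clerical_support" = 14,
      "craft_trade_machine" = 8, "entrepreneur_freelancer" = 30,
      "manager" = 59, "none_or_undisclosed" = 34, "professional" = 227,
      "retired" = 39, "sales_services" = 29, "staying_at_home" = 5,
      "student" = 74, "technician_associate" = 90, "unemployed" = 19
    ) / 629,
    country = c(
      "unknown" = 91, "usa" = 199, "finland" = 66, "great_britain" = 32,
      "germany" = 42, "canada" = 16, "india" = 29, "other" = 154
    ) / 629
  )
}

# Country -> IANA timezone used when generating participant profiles.
.country_timezones <- list(
  usa = c("America/New_York", "America/Chicago", "America/Los_Angeles"),
  finland = "Europe/Helsinki",
  great_britain = "Europe/London",
  germany = "Europe/Berlin",
  canada = c("America/Toronto", "America/Vancouver"),
  india = "Asia/Kolkata",
  unknown = c("UTC", "Europe/Paris", "America/Sao_Paulo"),
  other = c(
    "Europe/Madrid", "Europe/Moscow", "Asia/Tokyo", "Australia/Sydney",
    "Africa/Johannesburg", "America/Mexico_City", "Asia/Manila"
  )
)

#' Probability mass function of synthetic PHQ-8 totals
#'
#' Builds the population distribution of PHQ-8 total scores (0-24) used by
#' the generator: a negative binomial matched by moments to the target
#' mean and standard deviation, truncated to 0-24, with the mass at and
#' above the clinical cut-off (total >= 10) rescaled so that
#' `P(total >= 10)` equals `prevalence` exactly.
#'
#' @param prevalence Target probability of a depressed score (total >= 10).
#' @param mean,sd Target mean and standard deviation of the total before
#'   the prevalence rescaling (defaults 5.19 and 5.22).
#' @return Numeric vector of length 25 (probabilities of totals 0..24).
#' @export
#' @examples
#' p <- phq8_total_pmf(0.1681)
#' sum(p[11:25]) # exactly 0.1681
phq8_total_pmf <- function(prevalence = 0.1681, mean = 5.19, sd = 5.22) {
  check_prob(prevalence, "prevalence")
  if (prevalence <= 0 || prevalence >= 1) {
    stop_config("`prevalence` must be strictly inside (0, 1)")
  }
  mu <- mean
  size <- mu^2 / (sd^2 - mu)
  p <- dnbinom(0:24, size = size, mu = mu)
  p <- p / sum(p)
  hi <- 11:25 # totals 10..24
  lo <- 1:10
  p[hi] <- p[hi] * prevalence / sum(p[hi])
  p[lo] <- p[lo] * (1 - prevalence) / sum(p[lo])
  p
}

# Moments of a pmf on 0..24 needed by the calibration.
.pmf_moments <- function(pmf) {
  k <- 0:24
  mu <- sum(k * pmf)
  v <- sum((k - mu)^2 * pmf)
  pi1 <- sum(pmf[11:25])
  mu_dep <- sum(k[11:25] * pmf[11:25]) / pi1
  list(
    mean = mu, sd = sqrt(v), prevalence = pi1,
    cov_label_total = pi1 * (mu_dep - mu)
  )
}

#' Calibrate the depressed-window entropy shift to a target correlation
#'
#' Solves, in closed form, for the standardized shift `entropy_effect`
#' (in day-level population SDs of screen-state normalized entropy) such
#' that the population Pearson correlation between the window-pooled
#' screen normalized entropy and the PHQ-8 total equals `target_r`.
#'
#' The generator's pooled feature is `eta_i + mean(eps_d) + delta * sigma_e
#' * L` with participant SD `sigma_b`, day SD `sigma_w`, day-level SD
#' `sigma_e = sqrt(sigma_b^2 + sigma_w^2)`, window label `L`, and an
#' average of `n_bar` days per window. With `c = cov(L, total)` and
#' `v = prevalence * (1 - prevalence)` taken from the configured total
#' distribution, the correlation identity
#' `r = delta * sigma_e * c / (sigma_pool * sigma_T)` with
#' `sigma_pool^2 = sigma_b^2 + (sigma_w^2 + sigma_m^2) / n_bar +
#' delta^2 sigma_e^2 v` (`sigma_m` = measurement noise of the
#' battery-sampled entropy reconstruction)
#' yields
#' `delta = r * sigma_T * sqrt(sigma_b^2 + (sigma_w^2 + sigma_m^2) / n_bar)
#'   / (sigma_e * sqrt(c^2 - r^2 v sigma_T^2))`.
#'
#' @param target_r Target population correlation (default 0.14).
#' @param prevalence,phq8_mean,phq8_sd Parameters of [phq8_total_pmf()].
#' @param entropy_between_sd,entropy_within_sd Between-participant and
#'   day-level SDs of the baseline normalized entropy.
#' @param entropy_meas_sd Day-level SD of the measurement noise added by
#'   battery-sampled carry-forward reconstruction of the screen state
#'   (default 0.10, matching ~100 sampling events/day).
#' @param mean_window_days Expected number of retained days per 14-day
#'   assessment window (default 13).
#' @return The standardized shift (a positive scalar for positive
#'   `target_r`).
#' @export
#' @examples
#' calibrate_entropy_effect(0.14)
calibrate_entropy_effect <- function(target_r = 0.14,
                                     prevalence = 0.1681,
                                     phq8_mean = 5.19,
                                     phq8_sd = 5.22,
                                     entropy_between_sd = 0.10,
                                     entropy_within_sd = 0.12,
                                     entropy_meas_sd = 0.10,
                                     mean_window_days = 13) {
  mom <- .pmf_moments(phq8_total_pmf(prevalence, phq8_mean, phq8_sd))
  sigma_e <- sqrt(entropy_between_sd^2 + entropy_within_sd^2)
  v <- mom$prevalence * (1 - mom$prevalence)
  c_lt <- mom$cov_label_total
  disc <- c_lt^2 - target_r^2 * v * mom$sd^2
  if (disc <= 0) {
    stop_config("`target_r` = %.3f is not attainable for this outcome distribution", target_r)
  }
  base_var <- entropy_between_sd^2 +
    (entropy_within_sd^2 + entropy_meas_sd^2) / mean_window_days
  target_r * mom$sd * sqrt(base_var) / (sigma_e * sqrt(disc))
}

#' Configuration of the synthetic smartphone-sensing study
#'
#' Assembles and validates every knob of the generator: cohort size and
#' follow-up length, battery-change sampling, missing-log behavior, PHQ-8
#' outcome distribution and dynamics, the depressed-window effects
#' injected into the behavioral streams, and demographic marginals.
#'
#' @param n_participants Number of participants.
#' @param days_range Integer pair: minimum and maximum days of follow-up
#'   per participant (minimum must be >= 8).
#' @param battery_events_per_day Mean number of scheduled battery-change
#'   sampling events per day (default 100, i.e. roughly one per 1% change).
#' @param missing_interval_rate Probability that a scheduled sampling event
#'   emits no log (a "missing log interval").
#' @param prevalence Target fraction of PHQ-8 totals >= 10.
#' @param entropy_effect Standardized shift (day-level SDs) in screen-state
#'   normalized entropy for days inside depressed assessment windows.
#'   `NULL` (default) calibrates it via [calibrate_entropy_effect()] to
#'   `target_r`.
#' @param target_r Population pooled-feature correlation used when
#'   `entropy_effect` is `NULL` (default 0.14).
#' @param nonlinear_effect_flag If `TRUE`, depressed windows additionally
#'   receive a non-monotone internet-regularity perturbation: each such
#'   window is pushed, with equal probability, to an extremely routine or
#'   an extremely erratic hourly connectivity pattern.
#' @param demographic_marginals Named list of named probability vectors;
#'   defaults to [default_demographic_marginals()].
#' @param app_catalog_size Number of distinct apps in the Zipf catalog.
#' @param icc Intraclass correlation of the latent severity (participant
#'   intercept variance share; default 0.7584).
#' @param ar1_rho AR(1) coefficient of the within-participant latent
#'   severity across consecutive 2-week windows.
#' @param phq8_mean,phq8_sd Moments of the PHQ-8 total distribution.
#' @param entropy_base_mean,entropy_between_sd,entropy_within_sd Mean,
#'   between-participant SD and day-level SD of baseline screen
#'   normalized entropy.
#' @param entropy_meas_sd Assumed day-level measurement-noise SD of the
#'   reconstructed entropy (used only by the calibration).
#' @param net_offline_hours Mean length (hours) of the nightly offline
#'   block in the internet-connectivity template.
#' @param net_flip_rate Baseline per-hour probability that a day deviates
#'   from the participant's connectivity template.
#' @param screen_switch_rate Mean number of screen on-segments per day.
#' @param app_rate Mean app launches per day (participant means are
#'   gamma-distributed around this).
#' @param mean_window_days Expected retained days per assessment window,
#'   used only by the analytic calibration.
#' @param seed Master seed; fully determines all generated output.
#' @return An object of class `synth_config` (a validated named list).
#' @export
#' @examples
#' cfg <- synth_config(n_participants = 20, seed = 7)
#' cfg$entropy_effect
synth_config <- function(n_participants = 629,
                         days_range = c(8L, 86L),
                         battery_events_per_day = 100,
                         missing_interval_rate = 0.02,
                         prevalence = 0.1681,
                         entropy_effect = NULL,
                         target_r = 0.14,
                         nonlinear_effect_flag = TRUE,
                         demographic_marginals = default_demographic_marginals(),
                         app_catalog_size = 100L,
                         icc = 0.7584,
                         ar1_rho = 0.6,
                         phq8_mean = 5.19,
                         phq8_sd = 5.22,
                         entropy_base_mean = 0.55,
                         entropy_between_sd = 0.10,
                         entropy_within_sd = 0.12,
                         entropy_meas_sd = 0.10,
                         net_offline_hours = 7,
                         net_flip_rate = 0.18,
                         screen_switch_rate = 18,
                         app_rate = 30,
                         mean_window_days = 13,
                         seed = 1L) {
  if (!is_scalar_number(n_participants) || n_participants < 0) {
    stop_config("`n_participants` must be a non-negative count")
  }
  if (length(days_range) != 2L || any(!is.finite(days_range)) ||
    days_range[1] > days_range[2]) {
    stop_config("`days_range` must be an increasing integer pair")
  }
  if (days_range[1] < 8) {
    stop_config("`days_range` minimum must be at least 8 days")
  }
  check_prob(missing_interval_rate, "missing_interval_rate")
  check_prob(prevalence, "prevalence")
  check_prob(icc, "icc")
  if (abs(ar1_rho) >= 1) stop_config("`ar1_rho` must be in (-1, 1)")
  if (!is.list(demographic_marginals) || is.null(names(demographic_marginals))) {
    stop_config("`demographic_marginals` must be a named list")
  }
  for (nm in names(demographic_marginals)) {
    check_marginal(demographic_marginals[[nm]], paste0("demographic_marginals$", nm))
  }
  if (!is_scalar_number(seed)) stop_config("`seed` must be a single integer")
  if (is.null(entropy_effect)) {
    entropy_effect <- calibrate_entropy_effect(
      target_r = target_r, prevalence = prevalence,
      phq8_mean = phq8_mean, phq8_sd = phq8_sd,
      entropy_between_sd = entropy_between_sd,
      entropy_within_sd = entropy_within_sd,
      entropy_meas_sd = entropy_meas_sd,
      mean_window_days = mean_window_days
    )
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    days_range = as.integer(days_range),
    battery_events_per_day = battery_events_per_day,
    missing_interval_rate = missing_interval_rate,
    prevalence = prevalence,
    entropy_effect = entropy_effect,
    target_r = target_r,
    nonlinear_effect_flag = isTRUE(nonlinear_effect_flag),
    demographic_marginals = demographic_marginals,
    app_catalog_size = as.integer(app_catalog_size),
    icc = icc,
    ar1_rho = ar1_rho,
    phq8_mean = phq8_mean,
    phq8_sd = phq8_sd,
    entropy_base_mean = entropy_base_mean,
    entropy_between_sd = entropy_between_sd,
    entropy_within_sd = entropy_within_sd,
    entropy_meas_sd = entropy_meas_sd,
    net_offline_hours = net_offline_hours,
    net_flip_rate = net_flip_rate,
    screen_switch_rate = screen_switch_rate,
    app_rate = app_rate,
    mean_window_days = mean_window_days,
    seed = as.integer(seed)
  )
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf(
    "  %d participants, %d-%d days, ~%g sampling events/day (%.1f%% missing)\n",
    x$n_participants, x$days_range[1], x$days_range[2],
    x$battery_events_per_day, 100 * x$missing_interval_rate
  ))
  cat(sprintf(
    "  PHQ-8: mean %.2f, sd %.2f, prevalence(>=10) %.4f, latent ICC %.4f\n",
    x$phq8_mean, x$phq8_sd, x$prevalence, x$icc
  ))
  cat(sprintf(
    "  effects: entropy shift %.4f SD%s; seed %d\n",
    x$entropy_effect,
    if (x$nonlinear_effect_flag) " + nonlinear internet-regularity" else "",
    x$seed
  ))
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' @param config A [synth_config()] object.
#' @param path File path.
#' @return `write_synth_config()` returns `path` invisibly;
#'   `read_synth_config()` returns a `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  x <- unclass(config)
  x$demographic_marginals <- lapply(x$demographic_marginals, as.list)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  if (!file.exists(path)) stop_config("config file `%s` does not exist", path)
  x <- yaml::read_yaml(path)
  # renormalize marginals against serialization round-off
  x$demographic_marginals <- lapply(x$demographic_marginals, function(m) {
    m <- unlist(m)
    m / sum(m)
  })
  x$days_range <- as.integer(unlist(x$days_range))
  do.call(synth_config, x)
}
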