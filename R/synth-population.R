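#' Generate a synthetic participant population
#'
#' Draws `n_participants` participant profiles whose demographic category
#' frequencies converge to the configured marginals, and assigns each
#' participant an IANA timezone consistent with their country.
#'
#' @param config A [synth_config()] object.
#' @return A tibble with one row per participant: `participant_id`,
#'   `timezone`, `age_group`, `gender`, `education`, `occupation`,
#'   `country`.
#' @export
#' @examples
#' profiles <- generate_population(synth_config(n_participants = 10, seed = 1))
#' profiles
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_participants
  m <- config$demographic_marginals
  with_seed(derive_seed(config$seed, 0L), {
    prof <- tibble(
      participant_id = sprintf("p%04d", seq_len(n)),
      age_group = sample_marginal(n, m$age_group),
      gender = sample_marginal(n, m$gender),
      education = sample_marginal(n, m$education),
      occupation = sample_marginal(n, m$occupation),
      country = sample_marginal(n, m$country)
    )
    prof$timezone <- vapply(prof$country, function(cc) {
      zones <- .country_timezones[[cc]]
      if (is.null(zones)) zones <- "UTC"
      if (length(zones) == 1L) zones else sample(zones, 1L)
    }, character(1), USE.NAMES = FALSE)
    dplyr::relocate(prof, "participant_id", "timezone")
  })
}
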