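#' One-hot encode age group and gender onto the analysis table
#'
#' Joins participant profiles and adds an indicator column per category
#' of the selected demographic variables (by default the 5 age groups
#' and 3 gender categories, i.e. 8 added columns). With
#' `variables = character(0)` the table is returned unchanged
#' (features-only mode).
#'
#' @param samples Pooled-sample tibble with `participant_id`.
#' @param profiles Participant profiles.
#' @param variables Demographic variables to encode.
#' @return `samples` with the indicator columns appended (named
#'   `<variable>_<category>`).
#' @export
one_hot_demographics <- function(samples, profiles,
                                 variables = c("age_group", "gender")) {
  if (length(variables) == 0L) return(samples)
  missing_vars <- setdiff(variables, names(profiles))
  if (length(missing_vars) > 0L) {
    stop_config("profiles lack demographic variable `%s`", missing_vars[1])
  }
  joined <- dplyr::left_join(
    samples, profiles[c("participant_id", variables)],
    by = "participant_id"
  )
  if (anyNA(joined[variables])) {
    stop_config("some samples have no matching participant profile")
  }
  marg <- default_demographic_marginals()
  for (v in variables) {
    levels <- if (v %in% names(marg)) names(marg[[v]]) else sort(unique(joined[[v]]))
    unknown <- setdiff(unique(joined[[v]]), levels)
    if (length(unknown) > 0L) {
      stop_config("unknown %s category `%s`", v, unknown[1])
    }
    for (lv in levels) {
      col <- paste0(v, "_", gsub("[^A-Za-z0-9]+", "_", lv))
      joined[[col]] <- as.integer(joined[[v]] == lv)
    }
    joined[[v]] <- NULL
  }
  joined
}
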