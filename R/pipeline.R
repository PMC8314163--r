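# One-command pipeline runner and plain-text report writer.

#' Cohort summary of PHQ-8 responses
#'
#' Participant/response accounting in the shape of the usual descriptive
#' tables: responses per participant, class split at the clinical
#' cut-off, and score moments.
#'
#' @param responses Response tibble with `participant_id`, `phq8_total`.
#' @return List: `n_participants`, `n_responses`,
#'   `mean_responses_per_participant`, `sd_responses_per_participant`,
#'   `response_distribution` (participants by response count),
#'   `class_split` (n and percentage below/at-or-above 10),
#'   `mean_total`, `sd_total`.
#' @export
summarize_phq8 <- function(responses) {
  per <- table(responses$participant_id)
  lab <- label_phq8(responses$phq8_total)
  dist <- as.data.frame(table(as.integer(per)), stringsAsFactors = FALSE)
  list(
    n_participants = length(per),
    n_responses = nrow(responses),
    mean_responses_per_participant = nrow(responses) / length(per),
    sd_responses_per_participant = sd(as.numeric(per)),
    response_distribution = tibble(
      n_responses = as.integer(dist$Var1), n_participants = dist$Freq,
      pct = 100 * dist$Freq / length(per)
    ),
    class_split = tibble(
      label = c(0L, 1L),
      n = c(sum(lab == 0), sum(lab == 1)),
      pct = 100 * c(mean(lab == 0), mean(lab == 1))
    ),
    mean_total = mean(responses$phq8_total),
    sd_total = sd(responses$phq8_total)
  )
}

#' Cohort summary of retained smartphone days
#'
#' @param days Day-summary or day-feature tibble with `participant_id`,
#'   `local_date`.
#' @param breaks Right-closed bin edges for the days-per-participant
#'   distribution (default the 2-week bins 8-14, 15-28, ...).
#' @return List: `n_days`, `n_participants`, `mean_days_per_participant`,
#'   `sd_days_per_participant`, `day_distribution`.
#' @export
summarize_days <- function(days, breaks = c(7, 14, 28, 42, 56, 70, 84, 98)) {
  per <- as.numeric(table(days$participant_id))
  bins <- cut(per, breaks = breaks)
  list(
    n_days = nrow(days),
    n_participants = length(per),
    mean_days_per_participant = nrow(days) / length(per),
    sd_days_per_participant = sd(per),
    day_distribution = tibble(
      bin = levels(bins), n_participants = as.integer(table(bins)),
      pct = 100 * as.integer(table(bins)) / length(per)
    )
  )
}

#' Run the full pipeline
#'
#' Executes generation, preprocessing, feature engineering, pooling,
#' statistics and (optionally) the nested-CV classification harness, and
#' writes all output tables, a run manifest and a plain-text summary
#' under `output_dir`.
#'
#' @param config A [synth_config()].
#' @param output_dir Output directory (created if needed).
#' @param cv A [cv_config()], or `NULL` to skip classification.
#' @param run_lmm Fit the per-feature mixed-model screen (default
#'   `TRUE`).
#' @param m_imputations Imputations for the mixed-model screen.
#' @param with_demographics Also evaluate the feature+demographics
#'   variant and the decision-tree baseline (default `TRUE` when `cv`
#'   is given).
#' @return Invisibly, a list with the run `manifest` and all in-memory
#'   results (`features`, `pooled`, `pearson`, `lmm`, `cv_features`,
#'   `cv_demographics`, `rwc`, `dt`).
#' @export
run_pipeline <- function(config, output_dir, cv = NULL, run_lmm = TRUE,
                         m_imputations = 20L, with_demographics = TRUE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- tic()
    val <- force(expr)
    timings[[name]] <<- round(tic() - s, 2)
    val
  }

  study <- stage("synth", simulate_study(config))
  days_all <- stage("segment", localize_and_segment(
    study$events, study$profiles, study$schedule
  ))
  days <- filter_days(days_all)
  responses <- filter_responses(study$responses, days)
  features <- stage("features", extract_features(days))
  pooled <- stage("pooling", {
    deduplicate_samples(pool_windows(features, responses))
  })

  pearson <- stage("pearson", pearson_with_holm(pooled))
  icc <- icc_components(pooled$phq8_total, pooled$participant_id)
  lmm <- NULL
  if (run_lmm) {
    lmm <- stage("lmm", {
      imp <- pmm_impute(pooled, m = m_imputations, seed = derive_seed(config$seed, 42L))
      lmm_associations(imp)
    })
  }

  cv_features <- cv_demographics <- dt <- NULL
  rwc <- rwc_baseline(pooled$label, seed = derive_seed(config$seed, 77L))
  pooled_cc <- pooled[complete.cases(pooled[feature_names()]), , drop = FALSE]
  if (!is.null(cv)) {
    cv_features <- stage("cv_features", nested_cv(pooled_cc, cv))
    if (with_demographics) {
      aug <- one_hot_demographics(pooled_cc, study$profiles)
      cv_demographics <- stage("cv_demographics", nested_cv(aug, cv))
      dt <- stage("dt_baseline", dt_baseline(aug, cv))
    }
  }

  # --- write outputs --------------------------------------------------
  paths <- c(
    features = "day_features.csv", pooled = "pooled_samples.csv",
    pearson = "association_pearson.csv"
  )
  readr::write_csv(features, file.path(output_dir, paths[["features"]]))
  readr::write_csv(pooled, file.path(output_dir, paths[["pooled"]]))
  readr::write_csv(pearson, file.path(output_dir, paths[["pearson"]]))
  if (!is.null(lmm)) {
    paths[["lmm"]] <- "association_lmm.csv"
    readr::write_csv(lmm, file.path(output_dir, paths[["lmm"]]))
  }
  for (nm in c("cv_features", "cv_demographics")) {
    rep <- get(nm)
    if (!is.null(rep)) {
      paths[[nm]] <- paste0(nm, "_metrics.csv")
      readr::write_csv(rep$summary, file.path(output_dir, paths[[nm]]))
      readr::write_csv(
        rep$importance, file.path(output_dir, paste0(nm, "_importance.csv"))
      )
    }
  }
  digests <- tools::md5sum(file.path(output_dir, unname(paths)))

  manifest <- list(
    seed = config$seed,
    config = unclass(config)[c(
      "n_participants", "days_range", "battery_events_per_day",
      "missing_interval_rate", "prevalence", "entropy_effect",
      "nonlinear_effect_flag", "app_catalog_size", "icc", "seed"
    )],
    counts = list(
      days_in = nrow(days_all), days_retained = nrow(days),
      responses_in = nrow(study$responses), responses_retained = nrow(responses),
      samples_pooled = nrow(pooled),
      samples_after_dedup = nrow(pooled),
      samples_complete_case = nrow(pooled_cc)
    ),
    icc = icc$icc,
    timings = timings,
    total_elapsed = round(tic() - t0, 2),
    digests = as.list(unname(digests)) |> setNames(basename(names(digests)))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  results <- list(
    manifest = manifest, study = study, features = features, pooled = pooled,
    pearson = pearson, icc = icc, lmm = lmm, cv_features = cv_features,
    cv_demographics = cv_demographics, rwc = rwc, dt = dt
  )
  write_summary(results, file.path(output_dir, "summary.txt"))
  invisible(results)
}

#' Write the plain-text study report
#'
#' Renders the participant/response distribution tables, the class
#' split, association tables, classifier metric tables (x100 scale,
#' mean (SD)) including the random-weighted and decision-tree baselines,
#' and the permutation-importance ranking.
#'
#' @param results A [run_pipeline()] result list (or a compatible subset
#'   with `pooled`, `features`, and optional model results).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(fmt, ...) writeLines(sprintf(fmt, ...), con)

  w("Smartphone behavioral markers and PHQ-8 depression: run summary")
  w("================================================================")
  resp <- results$pooled
  s <- summarize_phq8(resp[c("participant_id", "phq8_total")])
  w("")
  w("PHQ-8 responses (retained, pooled): %d from %d participants", s$n_responses, s$n_participants)
  w("Mean responses/participant: %.2f (SD %.2f)", s$mean_responses_per_participant,
    s$sd_responses_per_participant
  )
  w("Mean PHQ-8 total: %.2f (SD %.2f)", s$mean_total, s$sd_total)
  w(
    "Class split: %d nondepressed (%.2f%%), %d depressed (%.2f%%)",
    s$class_split$n[1], s$class_split$pct[1], s$class_split$n[2], s$class_split$pct[2]
  )
  if (!is.null(results$features)) {
    d <- summarize_days(results$features)
    w("Retained days: %d (mean %.1f/participant)", d$n_days, d$mean_days_per_participant)
  }
  if (!is.null(results$icc)) {
    w("")
    w("ICC of PHQ-8 total (random intercept): %.4f", results$icc$icc)
  }
  if (!is.null(results$pearson)) {
    w("")
    w("Pearson correlation screen (Holm-adjusted):")
    top <- dplyr::arrange(results$pearson, .data$p_adjusted)
    for (i in seq_len(min(5L, nrow(top)))) {
      w(
        "  %-24s r = %+.3f  p_adj = %.4g", top$feature[i], top$estimate[i],
        top$p_adjusted[i]
      )
    }
  }
  if (!is.null(results$lmm)) {
    w("")
    w("Mixed-model screen (BH-adjusted):")
    top <- dplyr::arrange(results$lmm, .data$p_adjusted)
    for (i in seq_len(min(5L, nrow(top)))) {
      w(
        "  %-24s beta = %+.3f  p_adj = %.4g", top$feature[i], top$estimate[i],
        top$p_adjusted[i]
      )
    }
  }
  fmt_cv <- function(rep, title) {
    w("")
    w("%s (x100, mean (SD) over %d folds):", title, rep$config$outer_folds)
    sm <- rep$summary
    for (cl in unique(sm$classifier)) {
      row <- sm[sm$classifier == cl, ]
      get <- function(m) {
        r <- row[row$metric == m, ]
        sprintf("%.2f (%.2f)", 100 * r$mean, 100 * r$sd)
      }
      w(
        "  %-4s acc %s  prec %s  rec %s  f1 %s  auc %s  kappa %s", cl,
        get("accuracy"), get("precision"), get("recall"), get("f1"),
        get("auc"), get("kappa")
      )
    }
  }
  if (!is.null(results$cv_features)) fmt_cv(results$cv_features, "Classifiers, features only")
  if (!is.null(results$cv_demographics)) {
    fmt_cv(results$cv_demographics, "Classifiers, features + demographics")
  }
  if (!is.null(results$dt)) fmt_cv(results$dt, "Decision-tree demographic baseline")
  if (!is.null(results$rwc)) {
    w("")
    w("Random weighted baseline (%d draws, x100):", attr(results$rwc, "n_draws"))
    for (i in seq_len(nrow(results$rwc))) {
      w(
        "  %-9s %.2f (%.2f)", results$rwc$metric[i], 100 * results$rwc$mean[i],
        100 * results$rwc$sd[i]
      )
    }
  }
  if (!is.null(results$cv_features) && nrow(results$cv_features$importance) > 0L) {
    w("")
    w("Top permutation importances (mean AUC drop across folds):")
    imp <- results$cv_features$importance |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(importance = mean(.data$importance), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$importance))
    for (i in seq_len(min(8L, nrow(imp)))) {
      w("  %-24s %+.4f", imp$feature[i], imp$importance[i])
    }
  }
  invisible(path)
}
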