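# Imbalance-aware nested cross-validation harness.

#' Nested cross-validation configuration
#'
#' @param outer_folds Outer (evaluation) folds, default 10.
#' @param inner_folds Inner (grid-search) folds, default 3.
#' @param classifiers Character subset of
#'   `c("rf", "svm", "xgb", "knn", "lr")` (plus `"dt"` for the
#'   demographic baseline).
#' @param grids Named list of hyperparameter data frames; defaults to
#'   [default_grids()].
#' @param smote_enabled Balance training partitions with [smote()]
#'   (default `TRUE`).
#' @param smote_k SMOTE neighbor count, default 5.
#' @param permutation_repeats Shuffles per feature for permutation
#'   importance, default 5.
#' @param group_folds If `TRUE`, outer and inner folds are
#'   participant-grouped ([grouped_folds()]); the default `FALSE`
#'   reproduces record-level stratified folding.
#' @param seed Master seed; fold assignment, SMOTE and learners derive
#'   sub-seeds from it.
#' @return A `cv_config` list.
#' @export
cv_config <- function(outer_folds = 10L, inner_folds = 3L,
                      classifiers = c("rf", "svm", "xgb", "knn", "lr"),
                      grids = default_grids(), smote_enabled = TRUE,
                      smote_k = 5L, permutation_repeats = 5L,
                      group_folds = FALSE, seed = 1L) {
  if (outer_folds < 2L || inner_folds < 2L) {
    stop_config("outer_folds and inner_folds must both be >= 2")
  }
  missing_grids <- setdiff(classifiers, names(grids))
  if (length(missing_grids) > 0L) {
    stop_config("no hyperparameter grid for classifier `%s`", missing_grids[1])
  }
  for (cl in classifiers) {
    if (nrow(grids[[cl]]) == 0L) stop_config("empty grid for classifier `%s`", cl)
  }
  structure(
    list(
      outer_folds = as.integer(outer_folds), inner_folds = as.integer(inner_folds),
      classifiers = classifiers, grids = grids,
      smote_enabled = isTRUE(smote_enabled), smote_k = as.integer(smote_k),
      permutation_repeats = as.integer(permutation_repeats),
      group_folds = isTRUE(group_folds), seed = as.integer(seed)
    ),
    class = "cv_config"
  )
}

# Balance + fit one training partition; returns model and the transform
# applied to feature matrices before prediction.
.fit_partition <- function(learner, x_train, y_train, params, config, seed) {
  transform <- identity
  if (.needs_scaling(learner)) {
    sc <- .standardizer(x_train)
    transform <- sc$apply
    x_train <- transform(x_train)
  }
  if (config$smote_enabled) {
    bal <- smote(x_train, y_train, k = config$smote_k, seed = seed)
    x_train <- as.matrix(bal$features)
    y_train <- bal$labels
  }
  model <- fit_learner(learner, x_train, y_train, params, seed = seed)
  list(model = model, transform = transform)
}

#' Permutation feature importance on held-out data
#'
#' The importance of a feature is the drop in midrank AUC when that
#' feature's column is shuffled in the held-out fold:
#' `AUC(original) - mean over repeats of AUC(shuffled)`. A feature the
#' model ignores (or a constant column) has importance 0 up to shuffle
#' noise.
#'
#' @param model Fitted learner (internal representation).
#' @param x_test Held-out feature matrix (already transformed as at
#'   training time).
#' @param y_test Held-out 0/1 labels.
#' @param repeats Shuffles per feature.
#' @param seed RNG seed.
#' @return Tibble `feature`, `importance`.
#' @export
permutation_importance <- function(model, x_test, y_test, repeats = 5L, seed = 1L) {
  base_auc <- auc_score(y_test, predict_prob(model, x_test, seed = seed))
  imp <- with_seed(seed, vapply(seq_len(ncol(x_test)), function(j) {
    drops <- vapply(seq_len(repeats), function(r) {
      xp <- x_test
      xp[, j] <- xp[, j][sample.int(nrow(xp))]
      base_auc - auc_score(y_test, predict_prob(model, xp, seed = seed + r))
    }, numeric(1))
    mean(drops)
  }, numeric(1)))
  tibble(feature = colnames(x_test), importance = imp)
}

#' Nested cross-validated evaluation
#'
#' Stratified `outer_folds`-fold evaluation with an inner
#' `inner_folds`-fold grid search per outer fold: for every candidate
#' hyperparameter setting, training partitions are balanced with SMOTE
#' (inside the inner split only), the setting with the best
#' macro-averaged F1 is selected, the model is refit on the full outer
#' training set (again SMOTE-balanced) and scored on the untouched outer
#' test fold. SMOTE and the grid search never see test rows; the driver
#' asserts train/test disjointness and logs the audit.
#'
#' @param samples Labeled analysis tibble (complete cases on the model
#'   columns) with `label` and `participant_id`.
#' @param config A [cv_config()].
#' @param features Feature columns to model (default: canonical features
#'   plus any one-hot demographic columns present).
#' @param importance Compute permutation importance per outer fold
#'   (default `TRUE`).
#' @return An object of class `cv_report`: list with `metrics`
#'   (classifier x fold), `summary` (mean/SD per classifier),
#'   `importance`, `selected` hyperparameters per fold, `folds`, and a
#'   leakage `audit` table.
#' @export
nested_cv <- function(samples, config = cv_config(), features = NULL,
                      importance = TRUE) {
  if (is.null(features)) {
    features <- c(
      intersect(feature_names(), names(samples)),
      grep("^(age_group|gender)_", names(samples), value = TRUE)
    )
  }
  x <- as.matrix(samples[features])
  if (any(!is.finite(x))) {
    stop_config("model matrix contains missing values; impute or complete-case first")
  }
  y <- samples$label
  folds <- if (config$group_folds) {
    grouped_folds(y, samples$participant_id, config$outer_folds, seed = config$seed)
  } else {
    stratified_folds(y, config$outer_folds, seed = config$seed)
  }

  metrics <- list()
  selected <- list()
  imp_list <- list()
  audit <- list()
  for (f in seq_len(config$outer_folds)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    stopifnot(length(intersect(train_idx, test_idx)) == 0L)
    audit[[f]] <- tibble(
      fold = f, n_train = length(train_idx), n_test = length(test_idx),
      disjoint = TRUE
    )
    y_tr <- y[train_idx]
    inner <- if (config$group_folds) {
      grouped_folds(y_tr, samples$participant_id[train_idx], config$inner_folds,
        seed = derive_seed(config$seed, 7000L + f)
      )
    } else {
      stratified_folds(y_tr, config$inner_folds,
        seed = derive_seed(config$seed, 7000L + f)
      )
    }
    for (cl in config$classifiers) {
      grid <- config$grids[[cl]]
      grid_score <- vapply(seq_len(nrow(grid)), function(g) {
        f1s <- vapply(seq_len(config$inner_folds), function(iv) {
          it <- train_idx[inner != iv]
          ival <- train_idx[inner == iv]
          fitted <- .fit_partition(
            cl, x[it, , drop = FALSE], y[it], grid[g, , drop = FALSE],
            config, derive_seed(config$seed, f * 1000L + g * 10L + iv)
          )
          p <- predict_prob(fitted$model, fitted$transform(x[ival, , drop = FALSE]))
          macro_f1(y[ival], as.integer(p >= 0.5))
        }, numeric(1))
        mean(f1s)
      }, numeric(1))
      best <- which.max(grid_score)
      fitted <- .fit_partition(
        cl, x[train_idx, , drop = FALSE], y_tr, grid[best, , drop = FALSE],
        config, derive_seed(config$seed, f * 1000L + 999L)
      )
      x_test <- fitted$transform(x[test_idx, , drop = FALSE])
      p <- predict_prob(fitted$model, x_test)
      ms <- metric_set(y[test_idx], as.integer(p >= 0.5), score = p)
      ms$classifier <- cl
      ms$fold <- f
      metrics[[length(metrics) + 1L]] <- ms
      selected[[length(selected) + 1L]] <- dplyr::bind_cols(
        tibble(classifier = cl, fold = f, inner_macro_f1 = grid_score[best]),
        as_tibble(grid[best, , drop = FALSE])
      )
      if (importance) {
        pi <- permutation_importance(
          fitted$model, x_test, y[test_idx],
          repeats = config$permutation_repeats,
          seed = derive_seed(config$seed, f * 1000L + 500L)
        )
        pi$classifier <- cl
        pi$fold <- f
        imp_list[[length(imp_list) + 1L]] <- pi
      }
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  metric_cols <- c("accuracy", "precision", "recall", "f1", "auc", "kappa")
  summary <- metrics |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$classifier, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
    )
  importance_tbl <- if (length(imp_list) > 0L) {
    dplyr::bind_rows(imp_list) |>
      dplyr::group_by(.data$classifier, .data$feature) |>
      dplyr::summarise(importance = mean(.data$importance), .groups = "drop") |>
      dplyr::arrange(.data$classifier, dplyr::desc(.data$importance))
  } else {
    tibble(classifier = character(0), feature = character(0), importance = numeric(0))
  }
  structure(
    list(
      metrics = metrics, summary = summary, importance = importance_tbl,
      selected = dplyr::bind_rows(selected), folds = folds,
      audit = dplyr::bind_rows(audit), config = config, features = features
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>\n")
  cat(sprintf(
    "  %d classifiers x %d outer folds (%s folding)\n",
    length(unique(x$metrics$classifier)), x$config$outer_folds,
    if (x$config$group_folds) "participant-grouped" else "record-level"
  ))
  s <- x$summary[x$summary$metric == "auc", ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s AUC %.2f (SD %.2f)\n", s$classifier[i],
      100 * s$mean[i], 100 * s$sd[i]
    ))
  }
  invisible(x)
}

#' Random weighted classifier baseline
#'
#' Distribution-matched random baseline: each of `n_draws` prediction
#' vectors draws labels i.i.d. from the empirical class proportions of
#' `labels`; the full metric set is computed per draw (AUC from the hard
#' 0/1 predictions with midrank ties) and averaged.
#'
#' @param labels Observed 0/1 labels.
#' @param n_draws Number of random prediction vectors, default 10000.
#' @param seed RNG seed.
#' @return Object of class `rwc_baseline`: tibble `metric`, `mean`,
#'   `sd`, `se` (on the 0-1 scale) plus attributes `n_draws`, `n`.
#' @export
#' @examples
#' rwc_baseline(rep(c(1, 0), c(20, 80)), n_draws = 200, seed = 1)
rwc_baseline <- function(labels, n_draws = 10000L, seed = 1L) {
  y <- as.integer(labels)
  n <- length(y)
  n1 <- sum(y == 1)
  n0 <- n - n1
  if (n1 == 0L || n0 == 0L) stop_config("both classes must be present")
  pi1 <- n1 / n
  with_seed(seed, {
    chunk <- 1000L
    sums <- NULL
    sq <- NULL
    done <- 0L
    while (done < n_draws) {
      b <- min(chunk, n_draws - done)
      pred <- matrix(rbinom(n * b, 1L, pi1), nrow = n)
      tp <- drop(crossprod(y, pred))
      predpos <- colSums(pred)
      fp <- predpos - tp
      fn <- n1 - tp
      tn <- n0 - fp
      acc <- (tp + tn) / n
      prec <- ifelse(predpos == 0, 0, tp / predpos)
      rec <- tp / n1
      f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
      auc <- (rec + tn / n0) / 2 # midrank AUC of hard predictions
      po <- acc
      pe <- (n1 / n) * (predpos / n) + (n0 / n) * ((n - predpos) / n)
      kap <- ifelse(abs(1 - pe) < 1e-15, 0, (po - pe) / (1 - pe))
      vals <- rbind(
        accuracy = acc, precision = prec, recall = rec,
        f1 = f1, auc = auc, kappa = kap
      )
      sums <- if (is.null(sums)) rowSums(vals) else sums + rowSums(vals)
      sq <- if (is.null(sq)) rowSums(vals^2) else sq + rowSums(vals^2)
      done <- done + b
    }
    mu <- sums / n_draws
    sdv <- sqrt(pmax(sq / n_draws - mu^2, 0) * n_draws / (n_draws - 1))
    structure(
      tibble(
        metric = names(mu), mean = unname(mu), sd = unname(sdv),
        se = unname(sdv / sqrt(n_draws))
      ),
      class = c("rwc_baseline", class(tibble())),
      n_draws = n_draws, n = n
    )
  })
}

#' Decision-tree demographic baseline
#'
#' The second benchmark: a decision tree evaluated with the same nested
#' cross-validation protocol as the main classifiers, but restricted to
#' the one-hot age-group and gender columns.
#'
#' @param samples Analysis tibble containing one-hot demographic columns
#'   (see [one_hot_demographics()]), `label`, `participant_id`.
#' @param config A [cv_config()]; its classifier set is overridden with
#'   `"dt"`.
#' @param importance Compute permutation importance (default `FALSE`).
#' @return A `cv_report` for the `dt` classifier.
#' @export
dt_baseline <- function(samples, config = cv_config(), importance = FALSE) {
  demo_cols <- grep("^(age_group|gender)_", names(samples), value = TRUE)
  if (length(demo_cols) == 0L) {
    stop_config("no one-hot demographic columns found; run one_hot_demographics()")
  }
  config$classifiers <- "dt"
  nested_cv(samples, config, features = demo_cols, importance = importance)
}
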