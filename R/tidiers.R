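# broom-style tidiers and ggplot2 methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an association screen
#'
#' @param x An `assoc_results` tibble ([pearson_with_holm()] or
#'   [lmm_associations()]).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `p.value`,
#'   `p.adjusted`, `method`.
#' @export
tidy.assoc_results <- function(x, ...) {
  tibble(
    term = x$feature, estimate = x$estimate, std.error = x$se,
    p.value = x$p_raw, p.adjusted = x$p_adjusted, method = x$method
  )
}

#' @rdname tidy.assoc_results
#' @export
glance.assoc_results <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_significant = sum(x$p_adjusted < 0.05, na.rm = TRUE),
    method = x$method[1]
  )
}

#' Tidy a nested-CV report
#'
#' `tidy()` returns the fold-level metrics in long form; `glance()` the
#' per-classifier mean/SD summary in wide form (one row per classifier).
#'
#' @param x A `cv_report` from [nested_cv()].
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) {
  tidyr::pivot_longer(
    x$metrics,
    cols = c("accuracy", "precision", "recall", "f1", "auc", "kappa"),
    names_to = "metric", values_to = "value"
  )[c("classifier", "fold", "metric", "value")]
}

#' @rdname tidy.cv_report
#' @export
glance.cv_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(
      names_from = "metric", values_from = c("mean", "sd"),
      names_glue = "{metric}_{.value}"
    )
}

#' Tidy an ICC decomposition
#'
#' @param x An `icc_result` from [icc_components()].
#' @param ... Unused.
#' @export
tidy.icc_result <- function(x, ...) {
  tibble(
    between_variance = x$between_variance,
    within_variance = x$within_variance,
    icc = x$icc, method = x$method
  )
}

#' Plot an association screen
#'
#' Dot plot of estimates with Wald 95% intervals, ordered by estimate;
#' features surviving the adjusted 0.05 threshold are highlighted.
#'
#' @param object An `assoc_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_results <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$estimate), , drop = FALSE]
  df$significant <- !is.na(df$p.adjusted) & df$p.adjusted < 0.05
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$estimate, y = stats::reorder(.data$term, .data$estimate),
      color = .data$significant
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(
        xmin = .data$estimate - 1.96 * .data$std.error,
        xmax = .data$estimate + 1.96 * .data$std.error
      ),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = if (object$method[1] == "pearson_holm") "Pearson r" else "standardized slope",
      y = NULL, color = "adj. p < .05"
    ) +
    ggplot2::theme_minimal()
}

#' Plot fold-level classifier metrics
#'
#' @param object A `cv_report`.
#' @param metrics Metrics to facet (default all six).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object,
                               metrics = c("accuracy", "precision", "recall", "f1", "auc", "kappa"),
                               ...) {
  df <- tidy(object)
  df <- df[df$metric %in% metrics, , drop = FALSE]
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$classifier, y = .data$value)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "fold metric") +
    ggplot2::theme_minimal()
}

#' Plot a permutation-importance ranking
#'
#' Mean AUC drop per feature across the outer folds, one panel per
#' classifier.
#'
#' @param report A `cv_report` with importance results.
#' @param top_n Show the `top_n` features per classifier.
#' @return A ggplot object.
#' @export
plot_importance <- function(report, top_n = 15L) {
  stopifnot(inherits(report, "cv_report"))
  order_overall <- report$importance |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(m = mean(.data$importance), .groups = "drop") |>
    dplyr::arrange(.data$m)
  imp <- report$importance |>
    dplyr::group_by(.data$classifier) |>
    dplyr::slice_max(.data$importance, n = top_n) |>
    dplyr::ungroup() |>
    dplyr::mutate(feature = factor(.data$feature, levels = order_overall$feature))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~classifier) +
    ggplot2::labs(x = "mean AUC drop when permuted", y = NULL) +
    ggplot2::theme_minimal()
}
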