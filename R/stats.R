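# Correlation and association analyses over pooled samples.

#' Holm and Benjamini-Hochberg p-value adjustment
#'
#' Thin, validated wrappers around the step-down (Holm, family-wise
#' error) and step-up (BH, false discovery rate) adjustments, returned in
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.03, 0.04))
#' bh_adjust(c(0.01, 0.02, 0.03))
holm_adjust <- function(p) {
  check_prob(p, "p")
  p.adjust(p, method = "holm")
}

#' @rdname holm_adjust
#' @export
bh_adjust <- function(p) {
  check_prob(p, "p")
  p.adjust(p, method = "BH")
}

#' Pearson correlation screen with Holm adjustment
#'
#' Correlates every feature with the PHQ-8 total on pairwise-complete
#' rows, then adjusts the p-values with the Holm step-down procedure.
#' Constant features have an undefined correlation and are reported as
#' missing, with a warning; they do not enter the adjustment family.
#'
#' @param samples Pooled-sample tibble (from [pool_windows()]).
#' @param features Feature columns to screen (default the canonical 22).
#' @param outcome Outcome column (default `"phq8_total"`).
#' @return Tibble of class `assoc_results`: `feature`, `estimate` (r),
#'   `se`, `p_raw`, `p_adjusted`, `n`, `method = "pearson_holm"`.
#' @export
pearson_with_holm <- function(samples, features = feature_names(),
                              outcome = "phq8_total") {
  features <- intersect(features, names(samples))
  y <- samples[[outcome]]
  res <- lapply(features, function(f) {
    x <- samples[[f]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warning(sprintf("feature `%s` is constant or has < 3 complete pairs; r undefined", f))
      return(tibble(
        feature = f, estimate = NA_real_, se = NA_real_,
        p_raw = NA_real_, n = n
      ))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    r <- unname(ct$estimate)
    tibble(
      feature = f, estimate = r,
      se = sqrt((1 - r^2) / (n - 2)), p_raw = unname(ct$p.value), n = n
    )
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_adjusted[ok] <- holm_adjust(out$p_raw[ok])
  out$method <- "pearson_holm"
  structure(out, class = c("assoc_results", class(out)))
}

#' Intraclass correlation from a random-intercept model
#'
#' Decomposes an outcome with repeated measures into between-group and
#' within-group variance under a random-intercept-only model and returns
#' `icc = between / (between + within)`, truncated at 0. The REML
#' estimator delegates to a mixed-model fit; the ANOVA estimator is the
#' classic one-way method-of-moments decomposition (with the
#' harmonic-style correction `n0` for unbalanced groups), useful as an
#' independent cross-check.
#'
#' @param outcome Numeric repeated-measures outcome.
#' @param group Grouping factor (participant ids).
#' @param method `"reml"` (default) or `"anova"`.
#' @return A list of class `icc_result`: `between_variance`,
#'   `within_variance`, `icc`, `method`.
#' @export
icc_components <- function(outcome, group, method = c("reml", "anova")) {
  method <- match.arg(method)
  group <- factor(group)
  ok <- is.finite(outcome) & !is.na(group)
  outcome <- outcome[ok]
  group <- droplevels(group[ok])
  sizes <- table(group)
  if (length(sizes) < 2L || all(sizes < 2L)) {
    stop_config("ICC needs >= 2 groups and at least one group with repeated measures")
  }
  if (method == "reml") {
    fit <- lme4::lmer(outcome ~ 1 + (1 | group),
      data = data.frame(outcome = outcome, group = group),
      control = lme4::lmerControl(check.conv.singular = "ignore")
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2b <- vc$vcov[vc$grp == "group"]
    s2w <- vc$vcov[vc$grp == "Residual"]
  } else {
    k <- length(sizes)
    n <- length(outcome)
    gm <- tapply(outcome, group, mean)
    ssb <- sum(sizes * (gm - mean(outcome))^2)
    ssw <- sum((outcome - gm[group])^2)
    msb <- ssb / (k - 1)
    msw <- ssw / (n - k)
    n0 <- (n - sum(sizes^2) / n) / (k - 1)
    s2w <- msw
    s2b <- max((msb - msw) / n0, 0)
  }
  structure(
    list(
      between_variance = s2b, within_variance = s2w,
      icc = if (s2b + s2w == 0) 0 else max(s2b, 0) / (s2b + s2w),
      method = method
    ),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC = %.4f (between %.4f, within %.4f; %s estimator)\n",
    x$icc, x$between_variance, x$within_variance, x$method
  ))
  invisible(x)
}

#' Multiple imputation by single-level predictive mean matching
#'
#' Fills missing feature cells with observed donor values. For each
#' imputation, an OLS predictive model for the target column (regressed
#' on the other feature columns, provisionally mean-filled, with
#' coefficients perturbed by a bootstrap refit) produces predicted means;
#' each missing cell receives the observed value of a donor drawn from
#' the `k` rows with the closest predicted mean. Imputed values therefore
#' always lie within the observed range of their column.
#'
#' @param samples Pooled-sample tibble; missingness is only permitted in
#'   feature columns.
#' @param m Number of imputed data sets (default 20).
#' @param k Number of donor candidates (default 5).
#' @param features Columns eligible for imputation.
#' @param seed RNG seed for the imputation draws.
#' @return A list of `m` completed tibbles (class `pmm_imputations`).
#' @export
pmm_impute <- function(samples, m = 20L, k = 5L, features = feature_names(),
                       seed = 1L) {
  features <- intersect(features, names(samples))
  x <- as.matrix(samples[features])
  if (any(colSums(!is.na(x)) == 0L)) {
    stop_config("column `%s` is entirely missing", features[colSums(!is.na(x)) == 0L][1])
  }
  na_cols <- features[colSums(is.na(x)) > 0L]
  if (length(na_cols) == 0L) {
    out <- rep(list(samples), m)
    return(structure(out, class = "pmm_imputations"))
  }
  col_means <- colMeans(x, na.rm = TRUE)
  x_filled <- x
  for (j in seq_along(features)) {
    x_filled[is.na(x_filled[, j]), j] <- col_means[j]
  }
  with_seed(seed, {
    out <- lapply(seq_len(m), function(imp) {
      xi <- x
      for (cn in na_cols) {
        miss <- is.na(x[, cn])
        obs <- which(!miss)
        preds <- setdiff(features, cn)
        # drop constant predictors to keep the OLS well-posed
        keep <- preds[apply(x_filled[obs, preds, drop = FALSE], 2L, sd) > 0]
        boot <- sample(obs, length(obs), replace = TRUE)
        if (length(keep) == 0L) {
          yhat_obs <- rep(mean(x[boot, cn]), length(obs))
          yhat_mis <- rep(mean(x[boot, cn]), sum(miss))
        } else {
          fit <- lm.fit(
            cbind(1, x_filled[boot, keep, drop = FALSE]),
            x[boot, cn]
          )
          beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          yhat_obs <- drop(cbind(1, x_filled[obs, keep, drop = FALSE]) %*% beta)
          yhat_mis <- drop(cbind(1, x_filled[miss, keep, drop = FALSE]) %*% beta)
        }
        for (ii in seq_len(sum(miss))) {
          d <- abs(yhat_obs - yhat_mis[ii])
          donors <- obs[order(d)[seq_len(min(k, length(obs)))]]
          xi[which(miss)[ii], cn] <- x[sample(donors, 1L), cn]
        }
      }
      done <- samples
      done[features] <- as.data.frame(xi)
      done
    })
    structure(out, class = "pmm_imputations")
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' `pooled estimate = mean(est)`, total variance
#' `T = W + (1 + 1/m) B` with `W` the mean within-imputation variance and
#' `B` the between-imputation variance of the estimates; the p-value is
#' the large-sample Wald test of the pooled estimate.
#'
#' @param estimates Per-imputation estimates.
#' @param variances Per-imputation squared standard errors.
#' @return List: `estimate`, `se`, `p`, `within`, `between`.
#' @export
#' @examples
#' rubin_pool(c(1, 3), c(1, 1)) # total variance 1 + 1.5 * 2 = 4
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(m >= 1L, length(variances) == m)
  est <- mean(estimates)
  w <- mean(variances)
  b <- if (m > 1L) var(estimates) else 0
  total <- w + (1 + 1 / m) * b
  se <- sqrt(total)
  list(
    estimate = est, se = se,
    p = 2 * pnorm(-abs(est / se)),
    within = w, between = b
  )
}

#' Bivariate linear mixed model pooled over imputations
#'
#' For one feature: in each completed data set, standardize the feature
#' (0 mean, unit SD), fit
#' `outcome ~ feature_z + (1 | participant)` with a mixed-model fitter,
#' and pool the fixed slope across imputations by [rubin_pool()].
#'
#' @param tables List of completed tibbles (e.g. [pmm_impute()] output).
#' @param feature Feature column name.
#' @param outcome Outcome column (default `"phq8_total"`).
#' @param group Grouping column (default `"participant_id"`).
#' @return One-row tibble: `feature`, `estimate` (pooled standardized
#'   slope), `se`, `p_raw`, `n_imputations`, `method = "lmm"`.
#' @export
fit_bivariate_lmm_pooled <- function(tables, feature, outcome = "phq8_total",
                                     group = "participant_id") {
  fits <- lapply(tables, function(tb) {
    df <- data.frame(
      y = tb[[outcome]],
      x = as.numeric(scale(tb[[feature]])),
      g = factor(tb[[group]])
    )
    tryCatch(
      {
        fit <- lme4::lmer(y ~ x + (1 | g),
          data = df,
          control = lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
        )
        list(
          beta = unname(lme4::fixef(fit)["x"]),
          var = as.matrix(stats::vcov(fit))["x", "x"]
        )
      },
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (sum(ok) <= length(fits) / 2) {
    return(tibble(
      feature = feature, estimate = NA_real_, se = NA_real_,
      p_raw = NA_real_, n_imputations = sum(ok), method = "lmm"
    ))
  }
  pooled <- rubin_pool(
    vapply(fits[ok], `[[`, numeric(1), "beta"),
    vapply(fits[ok], `[[`, numeric(1), "var")
  )
  tibble(
    feature = feature, estimate = pooled$estimate, se = pooled$se,
    p_raw = pooled$p, n_imputations = sum(ok), method = "lmm"
  )
}

#' Mixed-model association screen with BH adjustment
#'
#' Runs [fit_bivariate_lmm_pooled()] for every feature over the same
#' imputed data sets and adjusts the pooled p-values with the
#' Benjamini-Hochberg step-up procedure.
#'
#' @inheritParams fit_bivariate_lmm_pooled
#' @param features Feature columns to test.
#' @return Tibble of class `assoc_results` with `p_adjusted` and
#'   `method = "lmm_bh"`.
#' @export
lmm_associations <- function(tables, features = feature_names(),
                             outcome = "phq8_total", group = "participant_id") {
  features <- intersect(features, names(tables[[1]]))
  out <- dplyr::bind_rows(lapply(
    features, fit_bivariate_lmm_pooled,
    tables = tables, outcome = outcome, group = group
  ))
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_adjusted[ok] <- bh_adjust(out$p_raw[ok])
  out$method <- "lmm_bh"
  structure(out, class = c("assoc_results", class(out)))
}

#' Cluster-jackknife standard error of a Pearson correlation
#'
#' Delete-one-cluster jackknife SE of `cor(x, y)` for repeated-measures
#' data: the naive i.i.d. SE of r understates the sampling variance when
#' both variables cluster within participants.
#'
#' @param x,y Numeric vectors.
#' @param cluster Cluster (participant) id per observation.
#' @return The jackknife SE (scalar).
#' @export
pearson_cluster_se <- function(x, y, cluster) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  cluster <- cluster[ok]
  ids <- unique(cluster)
  g <- length(ids)
  if (g < 3L) stop_config("need at least 3 clusters for a jackknife SE")
  r_loo <- vapply(ids, function(id) {
    keep <- cluster != id
    cor(x[keep], y[keep])
  }, numeric(1))
  sqrt((g - 1) / g * sum((r_loo - mean(r_loo))^2))
}
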