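# Classifier registry. Fitting is delegated to established learners;
# every learner is wrapped behind a uniform fit/predict-probability
# interface so the cross-validation driver stays model-agnostic.
# Distance/margin learners (svm, knn, lr) receive features standardized
# with training-fold statistics; tree ensembles use raw features.

#' Default hyperparameter grids
#'
#' Per-classifier grids searched by the inner cross-validation:
#' random forest (`rf`): trees and maximum terminal nodes; RBF-kernel
#' SVM (`svm`): cost and gamma (`NA` gamma = the fitter's 1/p default);
#' gradient-boosted trees (`xgb`): depth, learning rate, rounds;
#' k-nearest neighbors (`knn`): k; L2-penalized logistic regression
#' (`lr`): penalty strength lambda; decision tree (`dt`, demographic
#' baseline): complexity and depth.
#'
#' @return Named list of parameter data frames.
#' @export
default_grids <- function() {
  list(
    rf = expand.grid(ntree = c(100L, 300L), maxnodes = c(NA, 1024L)),
    svm = expand.grid(cost = c(0.1, 1, 10), gamma = c(NA, 0.01)),
    xgb = expand.grid(
      max_depth = c(3L, 6L), eta = c(0.1, 0.3), nrounds = c(100L, 300L)
    ),
    knn = expand.grid(k = c(3L, 5L, 11L)),
    lr = expand.grid(lambda = c(0.001, 0.01, 0.1)),
    dt = expand.grid(cp = c(0.01, 0.05), maxdepth = c(3L, 6L))
  )
}

.needs_scaling <- function(learner) learner %in% c("svm", "knn", "lr")

# Fit one learner; `x` numeric matrix, `y` 0/1 vector.
fit_learner <- function(learner, x, y, params, seed = 1L) {
  yf <- factor(y, levels = c(0, 1))
  with_seed(seed, switch(learner,
    rf = {
      args <- list(x = x, y = yf, ntree = params$ntree)
      if (!is.na(params$maxnodes)) args$maxnodes <- params$maxnodes
      list(kind = "rf", fit = do.call(randomForest::randomForest, args))
    },
    svm = {
      args <- list(
        x = x, y = yf, kernel = "radial", cost = params$cost,
        probability = TRUE, scale = FALSE
      )
      if (!is.na(params$gamma)) args$gamma <- params$gamma
      list(kind = "svm", fit = do.call(e1071::svm, args))
    },
    xgb = {
      dm <- xgboost::xgb.DMatrix(x, label = y)
      list(kind = "xgb", fit = xgboost::xgb.train(
        params = list(
          objective = "binary:logistic", max_depth = params$max_depth,
          eta = params$eta, nthread = 1L, seed = seed
        ),
        data = dm, nrounds = params$nrounds, verbose = 0
      ))
    },
    knn = list(kind = "knn", x = x, y = yf, k = params$k),
    lr = list(kind = "lr", fit = glmnet::glmnet(
      x, yf,
      family = "binomial", alpha = 0, lambda = params$lambda
    )),
    dt = {
      df <- data.frame(y = yf, x)
      list(kind = "dt", fit = rpart::rpart(
        y ~ .,
        data = df, method = "class",
        control = rpart::rpart.control(cp = params$cp, maxdepth = params$maxdepth)
      ))
    },
    stop_config("unknown learner `%s`", learner)
  ))
}

# Positive-class probability predictions.
predict_prob <- function(model, x, seed = 1L) {
  switch(model$kind,
    rf = unname(predict(model$fit, x, type = "prob")[, "1"]),
    svm = {
      pr <- predict(model$fit, x, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    xgb = unname(predict(model$fit, xgboost::xgb.DMatrix(x))),
    knn = with_seed(seed, {
      pred <- class::knn(model$x, x, model$y, k = model$k, prob = TRUE)
      w <- attr(pred, "prob")
      unname(ifelse(pred == "1", w, 1 - w))
    }),
    lr = unname(drop(predict(model$fit, x, type = "response"))),
    dt = unname(predict(model$fit, data.frame(x), type = "prob")[, "1"]),
    stop_config("unknown model kind")
  )
}

# Train-fold standardization (applied to svm/knn/lr only).
.standardizer <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(apply = function(z) sweep(sweep(z, 2L, mu), 2L, sdv, "/"))
}
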