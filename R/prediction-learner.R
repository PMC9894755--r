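# Learner contract: a learner is a list with `name`, `fit(X, y, hp, seed)`
# and `predict(model, X)`; scores are probabilities in [0, 1]. The nested-CV
# framework is learner-agnostic, which keeps it testable with the
# deterministic stub learner below.

#' Gradient-boosted tree learner (xgboost)
#'
#' The default learner for the sPTB classifiers: a binary-logistic boosted
#' tree ensemble. Missing feature values pass through to the tree learner's
#' native default-direction handling.
#'
#' @return A learner object for [nested_cv()] and [fit_composite()].
#' @export
xgb_learner <- function() {
  ns <- getNamespace("xgboost")
  booster_create <- get("XGBoosterCreate_R", envir = ns)
  booster_update <- get("XGBoosterUpdateOneIter_R", envir = ns)
  set_params <- get("xgb.model.parameters<-", envir = ns)
  get_handle <- get("xgb.get.handle", envir = ns)
  list(
    name = "xgboost",
    fit = function(X, y, hp, seed) {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      params <- list(
        objective = "binary:logistic",
        max_depth = hp$max_depth %||% 3L,
        eta = hp$eta %||% 0.2,
        subsample = hp$subsample %||% 1,
        colsample_bytree = hp$colsample %||% 1,
        min_child_weight = hp$min_child_weight %||% 1,
        lambda = hp$lambda %||% 1,
        tree_method = "hist",
        max_bin = 16,
        nthread = 1,
        seed = seed
      )
      # direct booster construction + update loop: identical model to
      # xgb.train(params, dtrain, nrounds) without the per-call wrapper cost,
      # which matters inside the 60k-fit tuning loop
      model <- .Call(booster_create, list(dtrain))
      model <- set_params(model, params)
      h <- get_handle(model)
      for (i in seq_len(hp$nrounds %||% 30L)) {
        .Call(booster_update, h, as.integer(i - 1L), dtrain)
      }
      list(model = model, feature_names = colnames(X))
    },
    predict = function(fit, X) {
      d <- xgboost::xgb.DMatrix(X, nthread = 1)
      as.numeric(predict(fit$model, d))
    }
  )
}

#' Deterministic stub learner for framework tests
#'
#' A regularized difference-of-class-means linear scorer: fast, free of
#' randomness, and sufficient to exercise every contract of the
#' cross-validation machinery (fold sterility, composite pooling,
#' reclassification) without boosting-round noise.
#'
#' @return A learner object.
#' @export
stub_learner <- function() {
  list(
    name = "stub",
    fit = function(X, y, hp, seed) {
      Xi <- X
      mu <- colMeans(Xi, na.rm = TRUE)
      mu[is.na(mu)] <- 0
      for (j in seq_len(ncol(Xi))) Xi[is.na(Xi[, j]), j] <- mu[j]
      s <- apply(Xi, 2L, sd)
      s[s == 0 | !is.finite(s)] <- 1
      w <- (colMeans(Xi[y == 1, , drop = FALSE]) -
              colMeans(Xi[y == 0, , drop = FALSE])) / s^2
      w[!is.finite(w)] <- 0
      list(w = w, mu = mu, feature_names = colnames(X))
    },
    predict = function(fit, X) {
      for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- fit$mu[j]
      as.numeric(plogis(drop(X %*% fit$w)))
    }
  )
}
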