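## Interpretable additive boosted learner.
##
## All classifiers in the package share one architecture: gradient boosting
## restricted to depth-one trees (stumps). Because every tree splits on a
## single feature, the fitted model is additive in its features -- the same
## structural property that makes explainable boosting machines inspectable
## -- and per-feature shape functions can be read off by accumulating each
## feature's stumps.

#' Fit an additive boosted classifier (depth-one trees)
#'
#' @param x numeric feature matrix.
#' @param y labels: 0/1 for binary, or a factor for multiclass.
#' @param nrounds boosting rounds.
#' @param eta learning rate.
#' @param seed integer seed passed to the booster.
#' @return an object of class `additive_boost` with the fitted booster, the
#'   feature names and the class levels.
#' @export
fit_additive_boost <- function(x, y, nrounds = 200L, eta = 0.1, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.factor(y) || is.character(y)) {
    lev <- levels(factor(y))
    yy <- as.integer(factor(y, levels = lev)) - 1L
    params <- list(max_depth = 1L, eta = eta, objective = "multi:softprob",
                   num_class = length(lev), nthread = 1L, seed = seed,
                   tree_method = "exact")
  } else {
    lev <- NULL
    yy <- as.numeric(y)
    stopifnot(all(yy %in% c(0, 1)))
    params <- list(max_depth = 1L, eta = eta, objective = "binary:logistic",
                   nthread = 1L, seed = seed, tree_method = "exact")
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = yy)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, features = colnames(x), classes = lev,
                 nrounds = nrounds, eta = eta),
            class = "additive_boost")
}

#' Predict from an additive boosted classifier
#'
#' @param object an [fit_additive_boost()] model.
#' @param x feature matrix (columns are aligned by name to the training
#'   features).
#' @param ... unused.
#' @return binary models: vector of case probabilities; multiclass models: a
#'   probability matrix with one column per class (rows sum to 1).
#' @export
predict.additive_boost <- function(object, x, ...) {
  x <- as.matrix(x)
  if (!is.null(object$features)) {
    missing <- setdiff(object$features, colnames(x))
    if (length(missing)) stop("missing features: ",
                              paste(missing, collapse = ", "))
    x <- x[, object$features, drop = FALSE]
  }
  storage.mode(x) <- "double"
  p <- predict(object$booster, xgboost::xgb.DMatrix(x))
  if (is.null(object$classes)) return(as.numeric(p))
  m <- if (is.matrix(p)) p else matrix(p, ncol = length(object$classes),
                                       byrow = TRUE)
  colnames(m) <- object$classes
  m
}

#' Per-feature shape contributions of an additive boosted model
#'
#' Sums each depth-one tree's gain by the feature it splits on, giving a
#' global view of how strongly each feature shapes the additive model.
#'
#' @param object an [fit_additive_boost()] model.
#' @return a `data.table` with `feature` and `gain` (normalized to sum to 1).
#' @export
additive_boost_gains <- function(object) {
  imp <- xgboost::xgb.importance(model = object$booster)
  data.table(feature = imp$Feature, gain = imp$Gain)
}
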