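#' Learner adapter contract
#'
#' The ensemble-ranking harness consumes classifiers through a minimal
#' adapter: `fit(x, y, params, seed)` returns a fitted model;
#' `predict(model, x)` returns a per-sample case probability in \[0, 1\];
#' `importance(model)` returns a non-negative per-feature score vector of
#' length `ncol(x)`. The tree learners themselves come from established
#' implementations — the harness, aggregation and consensus logic are what
#' this package provides.
#'
#' @param name adapter label.
#' @param fit function `(x, y, params, seed) -> model` (x: numeric matrix,
#'   y: 0/1 integer vector).
#' @param predict function `(model, x) -> numeric` case probabilities.
#' @param importance function `(model) -> numeric` per-feature scores.
#' @return list of class `learner_adapter`.
#' @export
learner_adapter <- function(name, fit, predict, importance) {
  stopifnot(is.function(fit), is.function(predict), is.function(importance))
  structure(list(name = name, fit = fit, predict = predict,
                 importance = importance),
            class = "learner_adapter")
}

#' Random-forest adapter (ranger backend)
#'
#' Probability forest with impurity (Gini) importance. Grid parameters:
#' `mtry` (clamped to the number of SNPs, with a warning) and `ntree`.
#' Remaining parameters use the backend defaults.
#'
#' @param num_threads threads per fit (default 1 for determinism).
#' @return a [learner_adapter].
#' @export
adapter_rf <- function(num_threads = 1) {
  learner_adapter(
    name = "rf",
    fit = function(x, y, params, seed) {
      mtry <- params$mtry
      if (mtry > ncol(x)) {
        warning("mtry clamped from ", mtry, " to ", ncol(x))
        mtry <- ncol(x)
      }
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = params$ntree, mtry = mtry,
                     importance = "impurity", probability = TRUE,
                     seed = seed, num.threads = num_threads)
    },
    predict = function(model, x) {
      pr <- stats::predict(model, data = as.data.frame(x),
                           num.threads = 1)$predictions
      unname(pr[, "1"])
    },
    importance = function(model) {
      pmax(unname(ranger::importance(model)), 0)
    })
}

#' Gradient-boosted machine adapter (xgboost backend)
#'
#' Binary logistic boosting with improvement-weighted (gain) split
#' importance. Grid parameters: `n.trees` (boosting rounds),
#' `interaction.depth` (tree depth) and `shrinkage` (learning rate); fixed
#' settings follow common boosted-machine practice for this design: minimum
#' terminal-node size 10 (`min_child_weight`) and per-tree subsample
#' fraction 0.5.
#'
#' @param nthread threads per fit (default 1 for determinism).
#' @return a [learner_adapter].
#' @export
adapter_gbm <- function(nthread = 1) {
  learner_adapter(
    name = "gbm",
    fit = function(x, y, params, seed) {
      x <- as.matrix(x)
      colnames(x) <- sprintf("f%d", seq_len(ncol(x)))
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      booster <- with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$interaction.depth,
                      eta = params$shrinkage,
                      subsample = 0.5,
                      min_child_weight = 10,
                      nthread = nthread,
                      verbosity = 0),
        data = dtrain, nrounds = params$n.trees, verbose = 0))
      list(booster = booster, n_features = ncol(x))
    },
    predict = function(model, x) {
      x <- as.matrix(x)
      colnames(x) <- sprintf("f%d", seq_len(ncol(x)))
      as.numeric(stats::predict(model$booster, newdata = xgboost::xgb.DMatrix(x)))
    },
    importance = function(model) {
      imp <- numeric(model$n_features)
      tab <- tryCatch(xgboost::xgb.importance(model = model$booster),
                      error = function(e) NULL)
      if (!is.null(tab) && nrow(tab) > 0) {
        idx <- as.integer(sub("^f", "", tab$Feature))
        imp[idx] <- tab$Gain
      }
      imp
    })
}

#' Default tuning grids
#'
#' The forest grid crosses `mtry` in \{100, 200, 300, 500, 1000\} with
#' `ntree` in \{500, 1000, 2000\} (15 cells); the boosted-machine grid
#' crosses `n.trees` in \{100, 500, 1000, 2000\}, `interaction.depth` in
#' \{1, 2, 10\} and `shrinkage` in \{0.001, 0.01, 0.1\} (36 cells).
#'
#' @return data.frame with one row per grid cell.
#' @export
default_rf_grid <- function() {
  expand.grid(mtry = c(100, 200, 300, 500, 1000),
              ntree = c(500, 1000, 2000))
}

#' @rdname default_rf_grid
#' @export
default_gbm_grid <- function() {
  expand.grid(n.trees = c(100, 500, 1000, 2000),
              interaction.depth = c(1, 2, 10),
              shrinkage = c(0.001, 0.01, 0.1))
}
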