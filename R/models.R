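#' Specification of a QSPR regression model
#'
#' Supported kinds and their hyperparameters (defaults in parentheses are the
#' tuned values used throughout the pipeline):
#' * `mlr` -- multiple linear regression, no hyperparameters;
#' * `pls` -- partial least squares, `ncomp` (11);
#' * `svm_rbf` -- support vector regression with radial-basis kernel,
#'   `sigma` (0.015), `C` (2), `epsilon` (0.1);
#' * `rf` -- random forest, `mtry` (18), `n_trees` (500);
#' * `gbm` -- gradient boosting with depth-limited regression trees and
#'   squared-error loss, `n_trees` (100), `interaction_depth` (16),
#'   `shrinkage` (0.1), `min_node_obs` (10).
#'
#' @param kind One of `"mlr"`, `"pls"`, `"svm_rbf"`, `"rf"`, `"gbm"`.
#' @param hyperparams Named list overriding the defaults above.
#' @param seed Integer seed for stochastic learners.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("mlr", "pls", "svm_rbf", "rf", "gbm"),
                       hyperparams = list(), seed = 1) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    mlr = list(),
    pls = list(ncomp = 11),
    svm_rbf = list(sigma = 0.015, C = 2, epsilon = 0.1),
    rf = list(mtry = 18, n_trees = 500),
    gbm = list(n_trees = 100, interaction_depth = 16, shrinkage = 0.1,
               min_node_obs = 10))
  unknown <- setdiff(names(hyperparams), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hp <- utils::modifyList(defaults, hyperparams)
  if (length(hp) && any(unlist(hp[setdiff(names(hp), "epsilon")]) <= 0)) {
    stop("hyperparameters must be positive", call. = FALSE)
  }
  structure(list(kind = kind, hyperparams = hp, seed = as.integer(seed)),
            class = "model_spec")
}

#' Train a QSPR regression model
#'
#' @param spec A [model_spec()].
#' @param X Complete, preprocessed (centered/scaled) descriptor matrix.
#' @param y Numeric response (log Papp), one value per row.
#' @return An object of class `qspr_model` holding the fitted backend, the
#'   spec and the training column names. Predictions via [predict()] accept
#'   any matrix containing those columns in any order.
#' @export
train_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as_descriptor_matrix(X)
  if (anyNA(X)) stop("X must be complete", call. = FALSE)
  if (nrow(X) != length(y)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (nrow(X) < 2) stop("need at least 2 training rows", call. = FALSE)
  hp <- spec$hyperparams
  p <- ncol(X)
  fit <- switch(spec$kind,
    mlr = {
      co <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)$coefficients
      co[is.na(co)] <- 0  # collinear columns contribute nothing
      list(coefficients = co)
    },
    pls = {
      if (hp$ncomp > p) stop("ncomp exceeds the number of features",
                             call. = FALSE)
      mixOmics::pls(X, y, ncomp = hp$ncomp, mode = "regression",
                    scale = FALSE)
    },
    svm_rbf = kernlab::ksvm(X, y, type = "eps-svr", kernel = "rbfdot",
                            kpar = list(sigma = hp$sigma), C = hp$C,
                            epsilon = hp$epsilon, scaled = FALSE),
    rf = {
      if (hp$mtry > p) stop("mtry (", hp$mtry, ") exceeds the ", p,
                            " features", call. = FALSE)
      rf_fit(X, y, hp$n_trees, seed = spec$seed) |>
        (\(f) { f$call <- NULL; f })()
    },
    gbm = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(max_depth = hp$interaction_depth, eta = hp$shrinkage,
                      min_child_weight = hp$min_node_obs, subsample = 1,
                      colsample_bytree = 1, tree_method = "exact",
                      objective = "reg:squarederror", nthread = 1),
        data = dtrain, nrounds = hp$n_trees, verbose = 0)
    })
  structure(list(spec = spec, fit = fit, columns = colnames(X)),
            class = "qspr_model")
}

#' @export
predict.qspr_model <- function(object, newdata, ...) {
  X <- as_descriptor_matrix(newdata)
  check_columns(X, object$columns, "prediction matrix")
  X <- X[, object$columns, drop = FALSE]
  out <- switch(object$spec$kind,
    mlr = as.numeric(cbind(1, X) %*% object$fit$coefficients),
    pls = {
      pr <- stats::predict(object$fit, X)$predict
      as.numeric(pr[, 1, dim(pr)[3]])
    },
    svm_rbf = as.numeric(kernlab::predict(object$fit, X)),
    rf = as.numeric(rf_predict(object$fit, X)),
    gbm = as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(X))))
  stats::setNames(out, rownames(X))
}

#' RMSE and R-squared of predictions
#'
#' R-squared is the squared Pearson correlation between observed and
#' predicted values. When either vector has zero variance the correlation is
#' undefined; `r2` is then `NA` and `r2_defined` is `FALSE` (with a warning).
#'
#' @param y Observed values.
#' @param y_hat Predicted values, same length (>= 2).
#' @return List with `rmse`, `r2`, `r2_defined`.
#' @export
evaluate_predictions <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  rmse <- sqrt(mean((y - y_hat)^2))
  if (stats::sd(y) == 0 || stats::sd(y_hat) == 0) {
    warning("zero variance in y or y_hat; r2 undefined", call. = FALSE)
    return(list(rmse = rmse, r2 = NA_real_, r2_defined = FALSE))
  }
  list(rmse = rmse, r2 = stats::cor(y, y_hat)^2, r2_defined = TRUE)
}

#' Cross-validation configuration
#'
#' @param folds Number of folds (>= 2, default 5).
#' @param repeats Number of repeats (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(folds = 5, repeats = 5, seed = 1) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed)), class = "cv_config")
}

#' Repeated k-fold cross-validation of a model spec
#'
#' Fold assignment is a seeded random balanced partition per repeat; metrics
#' are averaged over all folds x repeats (undefined fold R-squared values are
#' dropped from the mean).
#'
#' @param spec A [model_spec()].
#' @param X,y Training data as in [train_model()].
#' @param cv A [cv_config()].
#' @return List with mean `rmse` and `r2` across held-out folds.
#' @export
cross_validate <- function(spec, X, y, cv = cv_config()) {
  X <- as_descriptor_matrix(X)
  stopifnot(inherits(cv, "cv_config"))
  if (cv$folds > nrow(X)) stop("folds exceed the number of rows", call. = FALSE)
  set.seed(cv$seed)
  fold_sets <- make_folds(nrow(X), cv$folds, cv$repeats)
  rmses <- numeric(0); r2s <- numeric(0)
  for (folds in fold_sets) {
    for (k in seq_len(cv$folds)) {
      hold <- folds == k
      fit <- train_model(spec, X[!hold, , drop = FALSE], y[!hold])
      pred <- predict(fit, X[hold, , drop = FALSE])
      m <- suppressWarnings(evaluate_predictions(y[hold], pred))
      rmses <- c(rmses, m$rmse)
      r2s <- c(r2s, m$r2)
    }
  }
  list(rmse = mean(rmses), r2 = mean(r2s, na.rm = TRUE))
}

#' Grid search for hyperparameters by cross-validated RMSE
#'
#' @param kind Model kind, see [model_spec()].
#' @param grid List of named hyperparameter lists (grid points), tried in
#'   order; the point with the lowest mean CV RMSE wins, ties going to the
#'   earlier point.
#' @param X,y Training data.
#' @param cv A [cv_config()].
#' @param seed Seed passed to each candidate spec.
#' @return The winning [model_spec()], with the achieved CV RMSE in
#'   attribute `"cv_rmse"`.
#' @export
tune_model <- function(kind, grid, X, y, cv = cv_config(), seed = 1) {
  stopifnot(is.list(grid), length(grid) >= 1)
  scores <- vapply(grid, function(hp) {
    cross_validate(model_spec(kind, hp, seed = seed), X, y, cv)$rmse
  }, numeric(1))
  best <- which.min(scores)  # which.min takes the first on ties
  out <- model_spec(kind, grid[[best]], seed = seed)
  attr(out, "cv_rmse") <- scores[best]
  out
}

#' Train the SVM-RF-GBM linear stacking ensemble
#'
#' Fits the three base learners, collects their out-of-fold predictions under
#' the given cross-validation scheme (averaged over repeats), and regresses
#' the observed response on those predictions by least squares to obtain the
#' meta-coefficients. The base models are then refitted on the full training
#' data. If the out-of-fold predictions are collinear or constant, the
#' meta-coefficients fall back to the Moore-Penrose pseudo-inverse solution
#' and the model is flagged `degenerate`.
#'
#' @param X,y Training data as in [train_model()].
#' @param base_specs Named list of three [model_spec()]s; default SVM, RF and
#'   GBM at their tuned hyperparameters (RF `mtry` capped at the feature
#'   count).
#' @param cv A [cv_config()] for the out-of-fold predictions.
#' @return An object of class `qspr_ensemble`: `base` (trained models),
#'   `meta_coefficients` (intercept + one weight per base), `degenerate`.
#' @export
train_ensemble <- function(X, y, base_specs = NULL, cv = cv_config()) {
  X <- as_descriptor_matrix(X)
  if (is.null(base_specs)) {
    base_specs <- list(
      svm_rbf = model_spec("svm_rbf"),
      rf = model_spec("rf", list(mtry = min(18, ncol(X)))),
      gbm = model_spec("gbm"))
  }
  stopifnot(length(base_specs) >= 2, !is.null(names(base_specs)))
  set.seed(cv$seed)
  fold_sets <- make_folds(nrow(X), cv$folds, cv$repeats)
  oof <- matrix(0, nrow(X), length(base_specs),
                dimnames = list(rownames(X), names(base_specs)))
  for (folds in fold_sets) {
    for (k in seq_len(cv$folds)) {
      hold <- folds == k
      for (b in names(base_specs)) {
        fit <- train_model(base_specs[[b]], X[!hold, , drop = FALSE], y[!hold])
        oof[hold, b] <- oof[hold, b] +
          predict(fit, X[hold, , drop = FALSE]) / cv$repeats
      }
    }
  }
  D <- cbind(`(Intercept)` = 1, oof)
  co <- stats::lm.fit(D, y)$coefficients
  degenerate <- anyNA(co)
  if (degenerate) {
    warning("degenerate base predictions; using pseudo-inverse meta-fit",
            call. = FALSE)
    co <- as.numeric(MASS::ginv(D) %*% y)
    names(co) <- colnames(D)
  }
  base <- lapply(base_specs, function(s) train_model(s, X, y))
  structure(list(base = base, meta_coefficients = co,
                 degenerate = degenerate, columns = colnames(X)),
            class = "qspr_ensemble")
}

#' @export
predict.qspr_ensemble <- function(object, newdata, ...) {
  X <- as_descriptor_matrix(newdata)
  check_columns(X, object$columns, "prediction matrix")
  P <- vapply(object$base, predict, numeric(nrow(X)), newdata = X)
  if (nrow(X) == 1L) P <- matrix(P, 1, dimnames = list(rownames(X), names(object$base)))
  co <- object$meta_coefficients
  stats::setNames(as.numeric(co[1] + P %*% co[-1]), rownames(X))
}
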