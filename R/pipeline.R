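#' Configuration for a full training run
#'
#' Collects every tunable of the training workflow with the tuned settings as
#' defaults. Stage seeds are derived from `seed` by fixed offsets so a single
#' integer reproduces the whole run.
#'
#' @param split_ratio Training fraction of the 80:20 split.
#' @param split_bins Response-quantile strata for the split.
#' @param corr_threshold Absolute-correlation cutoff of the preprocessing
#'   filter.
#' @param rfe An [rfe_config()] (sizes clipped to the candidate count must be
#'   chosen by the caller).
#' @param ga A [ga_config()]; candidates are the RFE survivors.
#' @param run_ga Set `FALSE` to stop selection after RFE.
#' @param cv A [cv_config()] for model tuning/validation and ensemble
#'   stacking.
#' @param seed Global integer seed.
#' @param verbose Emit per-stage log lines via `message()`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(split_ratio = 0.8, split_bins = 5,
                       corr_threshold = 0.70,
                       rfe = rfe_config(), ga = ga_config(), run_ga = TRUE,
                       cv = cv_config(), seed = 1, verbose = TRUE) {
  structure(list(split_ratio = split_ratio, split_bins = split_bins,
                 corr_threshold = corr_threshold, rfe = rfe, ga = ga,
                 run_ga = run_ga, cv = cv, seed = as.integer(seed),
                 verbose = verbose),
            class = "run_config")
}

log_stage <- function(verbose, stage, t0, ...) {
  if (verbose) {
    message(sprintf("[%s] %s (%.1fs)", stage, paste0(..., collapse = ""),
                    as.numeric(Sys.time()) - t0))
  }
}

#' Run the full QSPR training workflow
#'
#' Executes, on training data only: stratified split, preprocessing fit,
#' RFE then GA descriptor selection, training of the five regressors and the
#' SVM-RF-GBM stacking ensemble, evaluation on the training set /
#' cross-validation / held-out test set, and the applicability-domain fit on
#' the selected, preprocessed training design with ensemble residuals.
#'
#' @param X Descriptor matrix for all compounds (may contain `NA`s).
#' @param y Named or positional numeric response, one value per row of `X`.
#' @param config A [run_config()].
#' @return A `run_bundle` list: `config`, `split`, `preprocess`,
#'   `rfe_result`, `ga_result`, `selected_columns`, `models` (five
#'   `qspr_model`s), `ensemble`, `metrics` (data frame, 6 models x
#'   RMSE/R2 for Train, CV, Test), `ad` (an `ad_model`), `manifest`.
#' @export
run_training <- function(X, y, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  X <- as_descriptor_matrix(X)
  stopifnot(nrow(X) == length(y))
  verbose <- config$verbose
  seed <- config$seed
  t0 <- as.numeric(Sys.time())

  split <- split_dataset(rownames(X), y, ratio = config$split_ratio,
                         n_bins = config$split_bins, seed = seed + 1L)
  tr <- rownames(X) %in% split$train_ids
  y_tr <- y[tr]; y_te <- y[!tr]
  log_stage(verbose, "split", t0, length(split$train_ids), " train / ",
            length(split$test_ids), " test")

  prep <- fit_preprocess(X[tr, , drop = FALSE],
                         corr_threshold = config$corr_threshold)
  Xtr <- apply_preprocess(prep, X[tr, , drop = FALSE])
  Xte <- apply_preprocess(prep, X[!tr, , drop = FALSE])
  log_stage(verbose, "preprocess", t0, length(prep$kept_columns),
            " descriptors kept")

  rfe_cfg <- config$rfe
  rfe_cfg$seed <- seed + 2L
  rfe_cfg$subset_sizes <- rfe_cfg$subset_sizes[
    rfe_cfg$subset_sizes <= ncol(Xtr)]
  rfe_res <- rfe_select(Xtr, y_tr, rfe_cfg)
  log_stage(verbose, "rfe", t0, length(rfe_res$selected_columns),
            " descriptors, cv rmse ", round(rfe_res$best_score, 3))

  if (config$run_ga) {
    ga_cfg <- config$ga
    ga_cfg$seed <- seed + 3L
    ga_res <- ga_select(Xtr[, rfe_res$selected_columns, drop = FALSE], y_tr,
                        ga_cfg)
    selected <- ga_res$selected_columns
    log_stage(verbose, "ga", t0, length(selected), " descriptors, cv rmse ",
              round(ga_res$best_score, 3))
  } else {
    ga_res <- NULL
    selected <- rfe_res$selected_columns
  }
  Xtr_s <- Xtr[, selected, drop = FALSE]
  Xte_s <- Xte[, selected, drop = FALSE]

  specs <- list(
    MLR = model_spec("mlr", seed = seed + 4L),
    PLS = model_spec("pls", list(ncomp = min(11, length(selected))),
                     seed = seed + 4L),
    SVM = model_spec("svm_rbf", seed = seed + 4L),
    RF = model_spec("rf", list(mtry = min(18, length(selected))),
                    seed = seed + 4L),
    GBM = model_spec("gbm", seed = seed + 4L))
  models <- lapply(specs, function(s) train_model(s, Xtr_s, y_tr))
  cv <- config$cv
  cv$seed <- seed + 5L
  ens <- train_ensemble(Xtr_s, y_tr,
                        base_specs = specs[c("SVM", "RF", "GBM")], cv = cv)
  log_stage(verbose, "models", t0, "5 base models + SVM-RF-GBM ensemble")

  all_models <- c(models, list(`SVM-RF-GBM` = ens))
  metrics <- do.call(rbind, lapply(names(all_models), function(nm) {
    m <- all_models[[nm]]
    pr_tr <- predict(m, Xtr_s); pr_te <- predict(m, Xte_s)
    e_tr <- evaluate_predictions(y_tr, pr_tr)
    e_te <- evaluate_predictions(y_te, pr_te)
    if (nm == "SVM-RF-GBM") {
      cv_m <- ensemble_cross_validate(Xtr_s, y_tr,
                                      specs[c("SVM", "RF", "GBM")], cv)
    } else {
      cv_m <- cross_validate(m$spec, Xtr_s, y_tr, cv)
    }
    data.frame(Model = nm,
               RMSE_Train = e_tr$rmse, R2_Train = e_tr$r2,
               RMSE_CV = cv_m$rmse, R2_CV = cv_m$r2,
               RMSE_Test = e_te$rmse, R2_Test = e_te$r2,
               stringsAsFactors = FALSE)
  }))
  log_stage(verbose, "metrics", t0, "6 models x train/cv/test")

  resid_tr <- y_tr - predict(ens, Xtr_s)
  ad <- fit_ad(Xtr_s, resid_tr)
  log_stage(verbose, "ad", t0, "h* = ", signif(ad$h_star, 3))

  manifest <- list(package_version = as.character(utils::packageVersion("caco2qspr")),
                   r_version = as.character(getRversion()),
                   seed = seed, n_train = sum(tr), n_test = sum(!tr),
                   n_selected = length(selected),
                   config_hash = config_hash(config))
  structure(list(config = config, split = split, preprocess = prep,
                 rfe_result = rfe_res, ga_result = ga_res,
                 selected_columns = selected, models = models,
                 ensemble = ens, metrics = metrics, ad = ad,
                 manifest = manifest),
            class = "run_bundle")
}

# nested cross-validation of the whole stacking procedure: within each
# held-out fold the meta-learner and bases are refit on the analysis fold
ensemble_cross_validate <- function(X, y, base_specs, cv) {
  set.seed(cv$seed + 1L)
  fold_sets <- make_folds(nrow(X), cv$folds, cv$repeats)
  rmses <- numeric(0); r2s <- numeric(0)
  inner <- cv_config(folds = cv$folds, repeats = 1, seed = cv$seed + 2L)
  for (folds in fold_sets) {
    for (k in seq_len(cv$folds)) {
      hold <- folds == k
      ens <- train_ensemble(X[!hold, , drop = FALSE], y[!hold], base_specs,
                            cv = inner)
      pred <- predict(ens, X[hold, , drop = FALSE])
      m <- suppressWarnings(evaluate_predictions(y[hold], pred))
      rmses <- c(rmses, m$rmse); r2s <- c(r2s, m$r2)
    }
  }
  list(rmse = mean(rmses), r2 = mean(r2s, na.rm = TRUE))
}

config_hash <- function(config) {
  # stable fingerprint without external digest dependencies
  s <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2147483647
}

#' Predict new compounds with a trained bundle
#'
#' Applies the bundle's preprocessing, predicts log Papp with the stacking
#' ensemble, computes leverages against the training applicability domain,
#' and assigns permeability classes to compounds inside the domain
#' (predictions outside it are reported but flagged and left unclassified).
#' When a property table is supplied, Ro5/Veber compliance and the eight
#' drug-likeness scores are appended.
#'
#' @param bundle A `run_bundle` from [run_training()].
#' @param X_new Descriptor matrix for the new compounds (must contain the
#'   selected descriptor columns; may contain `NA`s, imputed with training
#'   medians).
#' @param properties Optional property data frame with an `id` column
#'   matching `rownames(X_new)`.
#' @return A `prediction_report` list: `predictions` (data frame with id,
#'   predicted log Papp, leverage, `inside_ad`, `class`, and property-based
#'   columns when available) and `summary` (counts by class and domain
#'   status).
#' @export
run_prediction <- function(bundle, X_new, properties = NULL) {
  stopifnot(inherits(bundle, "run_bundle"))
  X_new <- as_descriptor_matrix(X_new)
  Xp <- apply_preprocess(bundle$preprocess, X_new)
  Xs <- Xp[, bundle$selected_columns, drop = FALSE]
  pred <- predict(bundle$ensemble, Xs)
  lev <- ad_leverage(bundle$ad, Xs)
  inside <- lev <= bundle$ad$h_star
  cls <- rep(NA_character_, nrow(Xs))
  cls[inside] <- as.character(classify_permeability(pred[inside]))
  out <- data.frame(id = rownames(Xs), log_papp_pred = as.numeric(pred),
                    leverage = as.numeric(lev), inside_ad = inside,
                    class = cls, stringsAsFactors = FALSE)
  if (!is.null(properties)) {
    stopifnot("id" %in% names(properties))
    idx <- match(out$id, properties$id)
    prof <- properties[idx, , drop = FALSE]
    out$ro5_compliant <- vapply(seq_len(nrow(prof)), function(i)
      ro5_compliant(prof[i, , drop = FALSE])$compliant, logical(1))
    out$veber_compliant <- vapply(seq_len(nrow(prof)), function(i)
      veber_compliant(prof[i, , drop = FALSE])$compliant, logical(1))
    out <- cbind(out, dls_table(prof))
  }
  summary <- list(n = nrow(out), n_inside = sum(inside),
                  n_outside = sum(!inside),
                  classes = if (any(inside))
                    summarize_classes(pred[inside]) else NULL)
  structure(list(predictions = out, summary = summary),
            class = "prediction_report")
}

#' PCA projection of a descriptor matrix
#'
#' Principal components of the column-centered data, for visualizing the
#' chemical space covered by training/testing sets. Component signs follow
#' the convention that each loading vector's largest-magnitude entry is
#' positive.
#'
#' @param X Complete descriptor matrix.
#' @param k Number of components, `k <= min(nrow - 1, ncol)`.
#' @return List with `scores` (n x k), `explained` (length-k fractions of
#'   total variance, non-increasing), `loadings`.
#' @export
pca_projection <- function(X, k = 2) {
  X <- as_descriptor_matrix(X)
  if (anyNA(X)) stop("X must be complete", call. = FALSE)
  if (k > min(nrow(X) - 1, ncol(X))) {
    stop("k exceeds min(nrow - 1, ncol)", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  ev <- pc$sdev^2
  list(scores = scores, explained = ev[seq_len(k)] / sum(ev),
       loadings = loadings)
}

#' Write the Table-1-style metrics CSV for a run bundle
#'
#' Columns: Model, RMSE_Train, R2_Train, RMSE_CV, R2_CV, RMSE_Test, R2_Test.
#'
#' @param bundle A `run_bundle`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(bundle, path) {
  stopifnot(inherits(bundle, "run_bundle"))
  df <- bundle$metrics
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write bundle artifacts (metrics, Williams data, manifest) to a directory
#'
#' @param bundle A `run_bundle`.
#' @param dir Output directory (created if absent).
#' @param X,y The matrix/response passed to [run_training()], used to
#'   recompute Williams data for the train and test sets.
#' @return `dir`, invisibly.
#' @export
write_bundle_artifacts <- function(bundle, dir, X, y) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metrics(bundle, file.path(dir, "metrics.csv"))
  X <- as_descriptor_matrix(X)
  tr <- rownames(X) %in% bundle$split$train_ids
  wtr <- williams_for_set(bundle, X[tr, , drop = FALSE], y[tr], "train")
  wte <- williams_for_set(bundle, X[!tr, , drop = FALSE], y[!tr], "test")
  w <- rbind(wtr, wte)
  utils::write.csv(w, file.path(dir, "williams.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(bundle$manifest,
      list(h_star = bundle$ad$h_star,
           n_outliers = sum(w$outlier),
           selected_columns = bundle$selected_columns)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

williams_for_set <- function(bundle, X, y, label) {
  Xs <- apply_preprocess(bundle$preprocess, X)[, bundle$selected_columns,
                                               drop = FALSE]
  williams_data(bundle$ad, Xs, y, predict(bundle$ensemble, Xs), label)
}
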