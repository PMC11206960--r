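#' Near-zero-variance columns
#'
#' Flags descriptors carrying (almost) no information: zero-variance columns,
#' and columns whose most common value dominates (frequency ratio of the two
#' most common values > `freq_cut`) while few distinct values exist
#' (distinct values < `unique_cut` percent of rows).
#'
#' @param m Numeric matrix (no missing values).
#' @param freq_cut Frequency-ratio cutoff (default 19, i.e. 95/5).
#' @param unique_cut Unique-value percentage cutoff (default 10).
#' @return Character vector of flagged column names.
#' @export
near_zero_variance <- function(m, freq_cut = 19, unique_cut = 10) {
  m <- as_descriptor_matrix(m)
  flagged <- vapply(colnames(m), function(j) {
    x <- m[, j]
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) == 1L) return(TRUE)  # constant
    freq_ratio <- tab[1] / tab[2]
    pct_unique <- 100 * length(tab) / length(x)
    freq_ratio > freq_cut && pct_unique < unique_cut
  }, logical(1))
  colnames(m)[flagged]
}

#' Deterministic pairwise-correlation filter
#'
#' Repeatedly finds the pair of columns with the largest absolute Pearson
#' correlation above `threshold` and removes the member with the larger mean
#' absolute correlation against all remaining columns; on an exact tie the
#' later column in input order is removed. Stops when no remaining pair
#' exceeds the threshold.
#'
#' @param m Numeric matrix with no missing values, >= 2 rows, and no
#'   zero-variance columns (remove those first).
#' @param threshold Absolute-correlation cutoff in (0, 1].
#' @return Character vector of kept column names, in input order.
#' @export
correlation_filter <- function(m, threshold = 0.70) {
  m <- as_descriptor_matrix(m)
  if (anyNA(m)) stop("correlation_filter requires a complete matrix",
                     call. = FALSE)
  if (nrow(m) < 2) stop("need >= 2 rows", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s) present: ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (ncol(m) < 2) return(colnames(m))
  C <- abs(stats::cor(m))
  diag(C) <- 0
  keep <- seq_len(ncol(m))
  repeat {
    sub <- C[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx <= threshold) break
    hit <- which(sub == mx, arr.ind = TRUE)[1, ]  # first pair in scan order
    i <- keep[hit[1]]; j <- keep[hit[2]]
    mean_i <- mean(C[i, setdiff(keep, i)])
    mean_j <- mean(C[j, setdiff(keep, j)])
    victim <- if (mean_i > mean_j) i else if (mean_j > mean_i) j else max(i, j)
    keep <- setdiff(keep, victim)
    if (length(keep) == 1L) break
  }
  colnames(m)[keep]
}

#' Fit the preprocessing model on a training matrix
#'
#' Computes, on training data only and in this order: per-column medians for
#' imputation (columns that are entirely missing are dropped), removal of
#' near-zero-variance columns, the pairwise-correlation filter, and
#' centering/scaling statistics for the surviving columns. The fitted model
#' is then applied unchanged to any matrix via [apply_preprocess()], so test
#' or prediction data never leak into the statistics.
#'
#' @param train Training descriptor matrix (may contain `NA`s).
#' @param corr_threshold Absolute Pearson correlation above which one of a
#'   descriptor pair is removed (default 0.70).
#' @param freq_cut,unique_cut Near-zero-variance parameters, see
#'   [near_zero_variance()].
#' @return An object of class `preprocess_model` with fields `medians`,
#'   `kept_columns`, `centers`, `scales`, `corr_threshold`, `nzv_params`.
#' @export
fit_preprocess <- function(train, corr_threshold = 0.70, freq_cut = 19,
                           unique_cut = 10) {
  train <- as_descriptor_matrix(train)
  if (nrow(train) < 2 || ncol(train) < 1) {
    stop("training matrix needs >= 2 rows and >= 1 column", call. = FALSE)
  }
  medians <- apply(train, 2, stats::median, na.rm = TRUE)
  usable <- names(medians)[!is.na(medians)]
  train <- train[, usable, drop = FALSE]
  medians <- medians[usable]
  for (j in usable) {
    miss <- is.na(train[, j])
    if (any(miss)) train[miss, j] <- medians[j]
  }
  nzv <- near_zero_variance(train, freq_cut, unique_cut)
  kept <- setdiff(colnames(train), nzv)
  # guard: exact-zero-sd columns that slipped past the nzv rule
  sds0 <- apply(train[, kept, drop = FALSE], 2, stats::sd)
  kept <- kept[sds0 > 0]
  kept <- correlation_filter(train[, kept, drop = FALSE], corr_threshold)
  centers <- colMeans(train[, kept, drop = FALSE])
  scales <- apply(train[, kept, drop = FALSE], 2, stats::sd)
  structure(list(medians = medians, kept_columns = kept, centers = centers,
                 scales = scales, corr_threshold = corr_threshold,
                 nzv_params = c(freq_cut = freq_cut, unique_cut = unique_cut)),
            class = "preprocess_model")
}

#' Apply a fitted preprocessing model
#'
#' Imputes with the training medians, keeps exactly the fitted columns, and
#' centers/scales with the training statistics. Row order is preserved.
#'
#' @param model A `preprocess_model` from [fit_preprocess()].
#' @param m Descriptor matrix containing every kept column.
#' @return Numeric matrix with columns `model$kept_columns`.
#' @export
apply_preprocess <- function(model, m) {
  stopifnot(inherits(model, "preprocess_model"))
  m <- as_descriptor_matrix(m)
  check_columns(m, model$kept_columns, "input matrix")
  out <- m[, model$kept_columns, drop = FALSE]
  for (j in model$kept_columns) {
    miss <- is.na(out[, j])
    if (any(miss)) out[miss, j] <- model$medians[j]
  }
  out <- sweep(out, 2, model$centers[model$kept_columns], "-")
  sweep(out, 2, model$scales[model$kept_columns], "/")
}

#' Serialize / restore a preprocessing model as JSON
#'
#' @param model A `preprocess_model`.
#' @param path JSON file path.
#' @return `write_preprocess_model()` returns `path` invisibly;
#'   `read_preprocess_model()` returns the restored model.
#' @export
write_preprocess_model <- function(model, path) {
  stopifnot(inherits(model, "preprocess_model"))
  payload <- list(medians = as.list(model$medians),
                  kept_columns = model$kept_columns,
                  centers = as.list(model$centers),
                  scales = as.list(model$scales),
                  corr_threshold = model$corr_threshold,
                  nzv_params = as.list(model$nzv_params))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preprocess_model
#' @export
read_preprocess_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(medians = unlist(raw$medians),
                 kept_columns = raw$kept_columns,
                 centers = unlist(raw$centers), scales = unlist(raw$scales),
                 corr_threshold = raw$corr_threshold,
                 nzv_params = unlist(raw$nzv_params)),
            class = "preprocess_model")
}

#' Stratified train/test split on the response
#'
#' Splits compound ids into training and testing sets at the requested ratio,
#' stratified on quantile bins of the response so both sets follow a
#' comparable log Papp distribution. Within each bin, `round(ratio x bin
#' size)` ids are drawn without replacement into the training set.
#'
#' @param ids Character vector of compound ids.
#' @param response Numeric response, same length as `ids`.
#' @param ratio Training fraction in (0, 1); default 0.8 for an 80:20 split.
#' @param n_bins Number of response-quantile strata (default 5).
#' @param seed Integer seed.
#' @return List with `train_ids` and `test_ids`, a disjoint partition of
#'   `ids`; both non-empty.
#' @export
split_dataset <- function(ids, response, ratio = 0.8, n_bins = 5, seed = 1) {
  stopifnot(length(ids) == length(response))
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)", call. = FALSE)
  if (length(ids) < n_bins) stop("need at least n_bins compounds", call. = FALSE)
  set.seed(as.integer(seed))
  breaks <- unique(stats::quantile(response, probs = seq(0, 1, length.out = n_bins + 1),
                                   na.rm = TRUE))
  bins <- if (length(breaks) > 2) {
    cut(response, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, length(response))
  train <- character(0)
  for (b in sort(unique(bins))) {
    members <- ids[bins == b]
    n_tr <- round(ratio * length(members))
    train <- c(train, if (n_tr > 0) sample(members, n_tr) else character(0))
  }
  test <- setdiff(ids, train)
  if (!length(train)) { train <- test[1]; test <- test[-1] }
  if (!length(test)) { test <- train[1]; train <- train[-1] }
  list(train_ids = train, test_ids = test)
}
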