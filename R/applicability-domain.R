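#' Fit a leverage-based applicability domain
#'
#' The applicability domain is defined on the (preprocessed) training design
#' augmented with an intercept column: the hat matrix is
#' H = X (X'X)^-1 X', a sample's leverage is the corresponding diagonal
#' entry, and the warning leverage is h* = 3(p + 1)/n for p predictors and n
#' training compounds. The inverse Gram matrix is computed by Moore-Penrose
#' pseudo-inverse so collinear descriptor sets remain well-defined.
#'
#' @param X_train Complete training descriptor matrix (n x p).
#' @param residuals Training residuals (observed - predicted log Papp) used
#'   to set the standardization scale.
#' @return An object of class `ad_model`: `inv_gram` ((p+1) x (p+1)),
#'   `h_star`, `n_train`, `p`, `residual_scale` (sample sd of the supplied
#'   residuals), `column_names`.
#' @export
fit_ad <- function(X_train, residuals) {
  X_train <- as_descriptor_matrix(X_train)
  if (anyNA(X_train)) stop("X_train must be complete", call. = FALSE)
  if (nrow(X_train) < 2) stop("empty or degenerate training matrix",
                              call. = FALSE)
  stopifnot(length(residuals) == nrow(X_train))
  D <- cbind(1, X_train)
  G <- crossprod(D)
  inv_gram <- MASS::ginv(G)
  inv_gram <- (inv_gram + t(inv_gram)) / 2  # enforce symmetry
  n <- nrow(X_train); p <- ncol(X_train)
  structure(list(inv_gram = inv_gram, h_star = 3 * (p + 1) / n,
                 n_train = n, p = p,
                 residual_scale = stats::sd(residuals),
                 column_names = colnames(X_train)),
            class = "ad_model")
}

#' Leverage of samples with respect to a fitted applicability domain
#'
#' For each intercept-augmented row u, the leverage is u' (X'X)^-1 u with X
#' the training design. For a row identical to a training row this equals
#' that row's training hat-matrix diagonal.
#'
#' @param ad An `ad_model` from [fit_ad()].
#' @param X_new Matrix containing the model's predictor columns (any order).
#' @return Named numeric vector of leverages, one per row.
#' @export
ad_leverage <- function(ad, X_new) {
  stopifnot(inherits(ad, "ad_model"))
  X_new <- as_descriptor_matrix(X_new)
  check_columns(X_new, ad$column_names, "leverage matrix")
  U <- cbind(1, X_new[, ad$column_names, drop = FALSE])
  stats::setNames(rowSums((U %*% ad$inv_gram) * U), rownames(X_new))
}

#' Standardized residuals under the training residual scale
#'
#' @param ad An `ad_model` with `residual_scale > 0`.
#' @param y Observed log Papp values.
#' @param y_hat Predicted log Papp values, same length.
#' @return (y - y_hat) / residual_scale.
#' @export
standardized_residuals <- function(ad, y, y_hat) {
  stopifnot(inherits(ad, "ad_model"), length(y) == length(y_hat))
  if (!is.finite(ad$residual_scale) || ad$residual_scale <= 0) {
    stop("residual_scale must be positive", call. = FALSE)
  }
  (y - y_hat) / ad$residual_scale
}

#' Williams-plot data with outlier flags
#'
#' One point per sample: leverage, standardized residual, and an outlier
#' flag raised when leverage exceeds the warning leverage h* or the
#' standardized residual magnitude exceeds 3 (the conventional Williams-plot
#' boundaries).
#'
#' @param ad An `ad_model`.
#' @param X Descriptor matrix with the model's predictor columns.
#' @param y,y_hat Observed and predicted responses (optional; residual
#'   columns are `NA` when omitted, and only leverage can flag outliers).
#' @param set_label Label stored in the `set` column (e.g. `"train"`,
#'   `"test"`, `"new"`).
#' @return Data frame `id`, `leverage`, `std_residual`, `set`, `outlier`,
#'   with attribute `"summary"` (h_star plus outlier counts).
#' @export
williams_data <- function(ad, X, y = NULL, y_hat = NULL, set_label = "train") {
  lev <- ad_leverage(ad, X)
  sr <- if (!is.null(y) && !is.null(y_hat)) {
    stopifnot(length(y) == nrow(X), length(y_hat) == nrow(X))
    standardized_residuals(ad, y, y_hat)
  } else rep(NA_real_, nrow(X))
  out <- data.frame(id = names(lev), leverage = as.numeric(lev),
                    std_residual = as.numeric(sr),
                    set = set_label,
                    outlier = lev > ad$h_star | (!is.na(sr) & abs(sr) > 3),
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- list(h_star = ad$h_star, n = nrow(out),
                               n_outliers = sum(out$outlier),
                               n_high_leverage = sum(lev > ad$h_star))
  out
}
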