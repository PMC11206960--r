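make_mat <- function(values, ...) {
  m <- cbind(...)
  rownames(m) <- sprintf("r%02d", seq_len(nrow(m)))
  m
}

test_that("training medians impute and all-missing columns are dropped", {
  m <- make_mat(, a = c(1, 2, NA, 4), b = c(0.3, 5, 2, 9),
                gone = c(NA, NA, NA, NA), c = c(1.4, -2, 0.5, 3))
  model <- fit_preprocess(m, corr_threshold = 0.99)
  expect_equal(unname(model$medians["a"]), 2)  # median of {1,2,4}
  expect_false("gone" %in% names(model$medians))
  out <- apply_preprocess(model, m)
  expect_false(anyNA(out))
  # the imputed cell sits at (median - mean)/sd of the imputed column
  imputed <- (2 - model$centers["a"]) / model$scales["a"]
  expect_equal(out[3, "a"], unname(imputed), ignore_attr = TRUE)
})

test_that("constant and near-constant columns are removed", {
  set.seed(2)
  m <- make_mat(, x = rnorm(100), const = rep(3.3, 100),
                nearconst = c(rep(1, 99), 2), y = rnorm(100))
  model <- fit_preprocess(m)
  expect_setequal(model$kept_columns, c("x", "y"))
})

test_that("near-zero-variance rule agrees with the caret implementation", {
  skip_if_not_installed("caret")
  set.seed(3)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    m <- cbind(a = rnorm(n),
               b = sample(c(0, 1), n, TRUE, prob = c(0.97, 0.03)),
               c = round(rnorm(n), sample(0:1, 1)),
               d = rep(sample(5, 1), n),
               e = sample(1:3, n, TRUE))
    rownames(m) <- seq_len(n)
    ours <- near_zero_variance(m)
    caret_idx <- caret::nearZeroVar(as.data.frame(m), freqCut = 19,
                                    uniqueCut = 10)
    expect_setequal(ours, colnames(m)[caret_idx])
  }
})

test_that("correlation filter keeps everything under the threshold and drops exact duplicates", {
  set.seed(4)
  m <- make_mat(, a = rnorm(50), b = rnorm(50), c = rnorm(50))
  expect_setequal(correlation_filter(m, 0.999), colnames(m))
  m2 <- cbind(m, dup = m[, "a"])
  kept <- correlation_filter(m2, 0.70)
  expect_length(intersect(c("a", "dup"), kept), 1)
})

test_that("the most-connected member of the worst pair is removed", {
  # A correlates strongly with both B and C; B and C correlate less.
  set.seed(5)
  n <- 400
  u <- rnorm(n); v <- rnorm(n)
  m <- make_mat(, A = u + v, B = u + 0.25 * v, C = v + 0.25 * u)
  C_abs <- abs(cor(m))
  expect_gt(C_abs["A", "B"], 0.70)
  expect_gt(C_abs["A", "C"], 0.70)
  expect_lt(C_abs["B", "C"], 0.70)
  kept <- correlation_filter(m, 0.70)
  expect_setequal(kept, c("B", "C"))
  expect_lte(max(abs(cor(m[, kept]))[upper.tri(diag(2))]), 0.70)
})

test_that("correlation filter matches the brute-force oracle on random matrices", {
  set.seed(6)
  for (i in 1:30) {
    n <- 60
    p <- sample(3:8, 1)
    m <- matrix(rnorm(n * p), n)
    # plant one or two correlated pairs
    for (k in seq_len(sample(1:2, 1))) {
      i1 <- sample(p, 1); i2 <- sample(setdiff(seq_len(p), i1), 1)
      m[, i2] <- m[, i1] + rnorm(n, 0, runif(1, 0.05, 0.8))
    }
    colnames(m) <- sprintf("v%d", seq_len(p))
    rownames(m) <- seq_len(n)
    kept <- correlation_filter(m, 0.70)
    expect_identical(sort(kept), sort(oracle_corr_filter(m, 0.70)))
    if (length(kept) > 1) {
      expect_lte(max(abs(cor(m[, kept]))[upper.tri(diag(length(kept)))]),
                 0.70)
    }
  }
})

test_that("zero-variance columns are rejected by the correlation filter", {
  m <- make_mat(, a = rnorm(10), z = rep(1, 10))
  expect_error(correlation_filter(m, 0.7), "zero-variance")
})

test_that("fit + apply standardizes the training matrix exactly", {
  set.seed(7)
  d <- generate_qspr_dataset(synthetic_spec(n_compounds = 150,
                                            n_noise = 10, n_redundant = 2,
                                            n_near_constant = 1, seed = 7))
  model <- fit_preprocess(d$matrix)
  out <- apply_preprocess(model, d$matrix)
  expect_true(all(abs(colMeans(out)) < 1e-10))
  expect_true(all(abs(apply(out, 2, sd) - 1) < 1e-10))
  expect_identical(out, apply_preprocess(model, d$matrix))
  # redundant columns fall to the correlation filter
  for (red in names(d$truth$redundant_map)) {
    pair <- c(red, d$truth$redundant_map[[red]])
    expect_lt(length(intersect(pair, model$kept_columns)), 2)
  }
})

test_that("apply_preprocess names any missing required column", {
  m <- make_mat(, a = rnorm(20), b = rnorm(20))
  model <- fit_preprocess(m, corr_threshold = 0.999)
  expect_error(apply_preprocess(model, m[, "a", drop = FALSE]), "b")
})

test_that("preprocess models survive a JSON round trip", {
  m <- make_mat(, a = c(1, 2, NA, 4, 5), b = c(0.3, 5, 2, 9, -1),
                c = rnorm(5))
  model <- fit_preprocess(m, corr_threshold = 0.95)
  f <- withr::local_tempfile(fileext = ".json")
  write_preprocess_model(model, f)
  back <- read_preprocess_model(f)
  expect_equal(back$medians, model$medians)
  expect_identical(back$kept_columns, model$kept_columns)
  expect_equal(back$centers, model$centers)
  expect_equal(back$scales, model$scales)
  expect_equal(apply_preprocess(back, m), apply_preprocess(model, m))
})

test_that("the stratified split is a seeded partition with balanced bins", {
  ids <- sprintf("c%04d", 1:1000)
  set.seed(8)
  y <- rnorm(1000)
  s1 <- split_dataset(ids, y, seed = 11)
  s2 <- split_dataset(ids, y, seed = 11)
  expect_identical(s1, s2)
  expect_setequal(c(s1$train_ids, s1$test_ids), ids)
  expect_length(intersect(s1$train_ids, s1$test_ids), 0)
  # per response-quantile bin, the train fraction is within one compound of 80%
  bins <- cut(y, quantile(y, seq(0, 1, 0.2)), include.lowest = TRUE)
  for (b in levels(bins)) {
    members <- ids[bins == b]
    n_tr <- sum(members %in% s1$train_ids)
    expect_lte(abs(n_tr - 0.8 * length(members)), 1)
  }
})

test_that("split edge cases: single bin and invalid ratio", {
  ids <- letters[1:10]
  s <- split_dataset(ids, rnorm(10), ratio = 0.8, n_bins = 1, seed = 1)
  expect_length(s$train_ids, 8)
  expect_length(s$test_ids, 2)
  expect_error(split_dataset(ids, rnorm(10), ratio = 1.2), "ratio")
})
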