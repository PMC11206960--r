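perfect_column_data <- function(seed, n = 120, p_noise = 20) {
  set.seed(seed)
  X <- matrix(rnorm(n * (p_noise + 1)), n)
  colnames(X) <- c("signal", sprintf("n%02d", seq_len(p_noise)))
  rownames(X) <- seq_len(n)
  list(X = X, y = X[, "signal"])
}

test_that("RFE finds a single perfect predictor among noise across seeds", {
  for (seed in 1:3) {
    d <- perfect_column_data(seed)
    res <- rfe_select(d$X, d$y, rfe_config(subset_sizes = 1:5, cv_repeats = 1,
                                           ranker_trees = 60, seed = seed))
    expect_identical(res$best_size, 1L)
    expect_identical(res$selected_columns, "signal")
    expect_equal(res$best_score, min(res$score_trace))
  }
})

test_that("RFE is deterministic and handles the degenerate all-columns grid", {
  d <- perfect_column_data(1, n = 80, p_noise = 6)
  cfg <- rfe_config(subset_sizes = 1:4, cv_repeats = 1, ranker_trees = 40,
                    seed = 5)
  r1 <- rfe_select(d$X, d$y, cfg)
  r2 <- rfe_select(d$X, d$y, cfg)
  expect_identical(r1, r2)
  p <- ncol(d$X)
  r_all <- rfe_select(d$X, d$y,
                      rfe_config(subset_sizes = p, cv_repeats = 1,
                                 ranker_trees = 40, seed = 5))
  expect_setequal(r_all$selected_columns, colnames(d$X))
  expect_length(r_all$score_trace, 1)
  expect_error(rfe_select(d$X, d$y, rfe_config(subset_sizes = p + 1)),
               "exceeds")
})

test_that("GA keeps a perfect singleton candidate and scores it near zero", {
  d <- perfect_column_data(2, n = 100, p_noise = 3)
  res <- ga_select(d$X, d$y,
                   ga_config(max_generations = 6, population_size = 10,
                             fitness_trees = 60, seed = 3))
  expect_true("signal" %in% res$selected_columns)
  expect_lt(res$best_score, 0.15)  # forest CV error of a perfect predictor
})

test_that("GA is deterministic, bounded by the full chromosome, and respects generation counts", {
  d <- perfect_column_data(3, n = 80, p_noise = 5)
  cfg <- ga_config(max_generations = 4, population_size = 8,
                   fitness_trees = 40, seed = 9)
  r1 <- ga_select(d$X, d$y, cfg)
  r2 <- ga_select(d$X, d$y, cfg)
  expect_identical(r1, r2)
  expect_length(r1$score_trace, 5)  # initial population + 4 generations
  expect_true(all(diff(r1$score_trace) <= 0))  # best-so-far never worsens
  # the GA can always retain the full subset, so it never does worse than it
  full_fit <- mean(replicate(3, {
    cv <- cv_config(folds = cfg$cv_folds, repeats = 1, seed = 1)
    cross_validate(model_spec("rf", list(mtry = 2, n_trees = 40)),
                   d$X, d$y, cv)$rmse
  }))
  expect_lte(r1$best_score, full_fit + 0.1)
  r0 <- ga_select(d$X, d$y,
                  ga_config(max_generations = 0, population_size = 8,
                            fitness_trees = 40, seed = 9))
  expect_length(r0$score_trace, 1)
})

test_that("RFE then GA recovers planted informative signals on strong-signal data", {
  for (seed in 1:3) {
    d <- generate_qspr_dataset(synthetic_spec(
      n_compounds = 500, n_informative = 5, n_redundant = 3, n_noise = 15,
      n_near_constant = 0, missing_fraction = 0, noise_sd = 0.3,
      seed = seed))
    prep <- fit_preprocess(d$matrix)
    X <- apply_preprocess(prep, d$matrix)
    rfe <- rfe_select(X, d$response,
                      rfe_config(subset_sizes = 1:10, cv_repeats = 1,
                                 ranker_trees = 80, seed = seed))
    ga <- ga_select(X[, rfe$selected_columns, drop = FALSE], d$response,
                    ga_config(max_generations = 8, population_size = 14,
                              fitness_trees = 80, seed = seed))
    # a surviving redundant alias carries the same signal as its source
    alias_of <- d$truth$redundant_map
    covered <- vapply(d$truth$informative_columns, function(ic) {
      ic %in% ga$selected_columns ||
        any(names(alias_of)[alias_of == ic] %in% ga$selected_columns)
    }, logical(1))
    expect_gte(sum(covered), 4)
    # at most one surviving duplicate pair: alias + source both selected
    dup_pairs <- sum(names(alias_of) %in% ga$selected_columns &
                       alias_of %in% ga$selected_columns)
    expect_lte(dup_pairs, 1)
  }
})

test_that("selection results serialize to JSON", {
  d <- perfect_column_data(4, n = 60, p_noise = 3)
  res <- rfe_select(d$X, d$y, rfe_config(subset_sizes = 1:2, cv_repeats = 1,
                                         ranker_trees = 30, seed = 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_selection_result(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(back$selected_columns, res$selected_columns)
  expect_equal(back$best_score, res$best_score)
})
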