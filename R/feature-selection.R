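#' Configuration for recursive feature elimination
#'
#' @param subset_sizes Integer vector of candidate subset sizes to score
#'   (default 1:200; clipped to the number of candidates at run time is an
#'   error, not silent).
#' @param cv_folds Cross-validation folds (>= 2, default 5).
#' @param cv_repeats Cross-validation repeats (default 20).
#' @param ranker_trees Trees in the random-forest ranker (default 100).
#' @param seed Integer seed.
#' @return An object of class `rfe_config`.
#' @export
rfe_config <- function(subset_sizes = 1:200, cv_folds = 5, cv_repeats = 20,
                       ranker_trees = 100, seed = 1) {
  stopifnot(all(subset_sizes >= 1), cv_folds >= 2, cv_repeats >= 1)
  structure(list(subset_sizes = sort(unique(as.integer(subset_sizes))),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 ranker_trees = as.integer(ranker_trees),
                 seed = as.integer(seed)),
            class = "rfe_config")
}

#' Configuration for genetic-algorithm feature selection
#'
#' Defaults are the full-scale search settings: 100 generations of a
#' population of 50 bit-string chromosomes, crossover probability 0.8,
#' per-bit mutation probability 0.1, no elitism, fitness scored by 5-fold
#' cross-validated RMSE of a random forest on the active subset.
#'
#' @param max_generations Number of generations to evolve (0 = score the
#'   random initial population only).
#' @param population_size Chromosomes per generation (>= 2).
#' @param crossover_prob Probability a mating pair undergoes uniform
#'   crossover.
#' @param mutation_prob Per-bit flip probability.
#' @param elitism Number of best chromosomes copied unchanged (default 0).
#' @param cv_folds Folds for the fitness cross-validation.
#' @param cv_repeats Repeats for the fitness cross-validation.
#' @param fitness_trees Trees in the fitness random forest (default 100).
#' @param seed Integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(max_generations = 100, population_size = 50,
                      crossover_prob = 0.8, mutation_prob = 0.1, elitism = 0,
                      cv_folds = 5, cv_repeats = 1, fitness_trees = 100,
                      seed = 1) {
  stopifnot(population_size >= 2, crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1, max_generations >= 0,
            elitism >= 0, cv_folds >= 2)
  structure(list(max_generations = as.integer(max_generations),
                 population_size = as.integer(population_size),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism = as.integer(elitism),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 fitness_trees = as.integer(fitness_trees),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Seeded fold ids: per repeat, a random balanced partition of n rows.
make_folds <- function(n, folds, repeats) {
  lapply(seq_len(repeats), function(r) sample(rep(seq_len(folds),
                                                  length.out = n)))
}

rf_fit <- function(X, y, trees, seed, importance = "none") {
  ranger::ranger(y = y, x = as.data.frame(X), num.trees = trees,
                 importance = importance, seed = seed, num.threads = 1)
}

rf_predict <- function(fit, X) {
  stats::predict(fit, data = as.data.frame(X), num.threads = 1)$predictions
}

#' Recursive feature elimination with a random-forest ranker
#'
#' For each cross-validation split, a random forest is fitted on all
#' candidate descriptors of the analysis fold and its permutation importances
#' rank the candidates; nested subsets at the configured sizes are then
#' scored by held-out RMSE. The winning size is the one with the smallest
#' mean RMSE across folds x repeats, and the final selected set is the top-k
#' descriptors of a ranker refitted on the full training data.
#'
#' @param X Complete (post-preprocessing) descriptor matrix.
#' @param y Numeric response, one value per row of `X`.
#' @param cfg An [rfe_config()].
#' @return An object of class `selection_result`: `selected_columns`,
#'   `score_trace` (named mean CV RMSE per size), `best_score`, `best_size`.
#' @export
rfe_select <- function(X, y, cfg = rfe_config()) {
  X <- as_descriptor_matrix(X)
  stopifnot(inherits(cfg, "rfe_config"), nrow(X) == length(y))
  if (anyNA(X)) stop("X must be complete (run preprocessing first)",
                     call. = FALSE)
  if (nrow(X) < cfg$cv_folds) stop("need at least cv_folds rows", call. = FALSE)
  sizes <- cfg$subset_sizes
  if (max(sizes) > ncol(X)) {
    stop("requested subset size ", max(sizes), " exceeds the ", ncol(X),
         " candidate columns", call. = FALSE)
  }
  set.seed(cfg$seed)
  fold_sets <- make_folds(nrow(X), cfg$cv_folds, cfg$cv_repeats)
  err <- matrix(NA_real_, length(sizes),
                cfg$cv_folds * cfg$cv_repeats,
                dimnames = list(as.character(sizes), NULL))
  split_idx <- 0L
  for (r in seq_len(cfg$cv_repeats)) {
    folds <- fold_sets[[r]]
    for (k in seq_len(cfg$cv_folds)) {
      split_idx <- split_idx + 1L
      hold <- folds == k
      Xa <- X[!hold, , drop = FALSE]; ya <- y[!hold]
      Xh <- X[hold, , drop = FALSE];  yh <- y[hold]
      ranker <- rf_fit(Xa, ya, cfg$ranker_trees,
                       seed = cfg$seed + 1000L * split_idx,
                       importance = "permutation")
      ranked <- names(sort(ranker$variable.importance, decreasing = TRUE))
      for (s in seq_along(sizes)) {
        keep <- ranked[seq_len(sizes[s])]
        fit <- rf_fit(Xa[, keep, drop = FALSE], ya, cfg$ranker_trees,
                      seed = cfg$seed + 1000L * split_idx + s)
        pred <- rf_predict(fit, Xh[, keep, drop = FALSE])
        err[s, split_idx] <- sqrt(mean((yh - pred)^2))
      }
    }
  }
  trace <- rowMeans(err)
  best_size <- sizes[which.min(trace)]
  final <- rf_fit(X, y, cfg$ranker_trees, seed = cfg$seed,
                  importance = "permutation")
  ranked <- names(sort(final$variable.importance, decreasing = TRUE))
  selected <- ranked[seq_len(best_size)]
  structure(list(selected_columns = selected, score_trace = trace,
                 best_score = min(trace), best_size = best_size),
            class = "selection_result")
}

# mean CV RMSE of a random forest on the active subset; the fitness of a
# chromosome (lower is better)
ga_fitness <- function(X, y, active, cfg, eval_id) {
  if (!any(active)) return(Inf)
  Xs <- X[, active, drop = FALSE]
  folds_sets <- make_folds(nrow(X), cfg$cv_folds, cfg$cv_repeats)
  errs <- numeric(0)
  for (folds in folds_sets) {
    for (k in seq_len(cfg$cv_folds)) {
      hold <- folds == k
      fit <- rf_fit(Xs[!hold, , drop = FALSE], y[!hold], cfg$fitness_trees,
                    seed = cfg$seed + eval_id)
      pred <- rf_predict(fit, Xs[hold, , drop = FALSE])
      errs <- c(errs, sqrt(mean((y[hold] - pred)^2)))
    }
  }
  mean(errs)
}

#' Genetic-algorithm descriptor-subset refinement
#'
#' Searches bit-string chromosomes over the candidate descriptors (typically
#' the RFE survivors). Fitness is the mean cross-validated RMSE of a random
#' forest on the active subset; empty chromosomes receive infinite (worst)
#' fitness. Evolution uses tournament selection (size 2), uniform crossover
#' and per-bit mutation, runs exactly `max_generations` generations, and
#' returns the best chromosome ever evaluated. Fitness values are cached by
#' chromosome, so re-evaluated subsets cost nothing.
#'
#' @inheritParams rfe_select
#' @param cfg A [ga_config()].
#' @return A `selection_result` with `score_trace` holding the best-so-far
#'   fitness after the initial population and after each generation
#'   (`max_generations + 1` entries).
#' @export
ga_select <- function(X, y, cfg = ga_config()) {
  X <- as_descriptor_matrix(X)
  stopifnot(inherits(cfg, "ga_config"), nrow(X) == length(y))
  if (ncol(X) < 1) stop("empty candidate set", call. = FALSE)
  if (anyNA(X)) stop("X must be complete (run preprocessing first)",
                     call. = FALSE)
  p <- ncol(X)
  set.seed(cfg$seed)
  pop <- matrix(stats::runif(cfg$population_size * p) < 0.5,
                cfg$population_size, p)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score_pop <- function(pop) {
    vapply(seq_len(nrow(pop)), function(i) {
      key <- paste(as.integer(pop[i, ]), collapse = "")
      if (!is.null(cache[[key]])) return(cache[[key]])
      n_eval <<- n_eval + 1L
      f <- ga_fitness(X, y, pop[i, ], cfg, n_eval)
      cache[[key]] <- f
      f
    }, numeric(1))
  }
  fit <- score_pop(pop)
  best_fit <- min(fit)
  best_chrom <- pop[which.min(fit), ]
  trace <- best_fit
  for (gen in seq_len(cfg$max_generations)) {
    newpop <- matrix(FALSE, cfg$population_size, p)
    row <- 0L
    if (cfg$elitism > 0) {
      elite <- order(fit)[seq_len(min(cfg$elitism, cfg$population_size))]
      for (e in elite) { row <- row + 1L; newpop[row, ] <- pop[e, ] }
    }
    tournament <- function() {
      pair <- sample(cfg$population_size, 2)
      pair[which.min(fit[pair])]
    }
    while (row < cfg$population_size) {
      p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
      if (stats::runif(1) < cfg$crossover_prob) {
        mask <- stats::runif(p) < 0.5
        c1 <- ifelse(mask, p1, p2); c2 <- ifelse(mask, p2, p1)
      } else { c1 <- p1; c2 <- p2 }
      for (child in list(c1, c2)) {
        if (row >= cfg$population_size) break
        flip <- stats::runif(p) < cfg$mutation_prob
        child[flip] <- !child[flip]
        row <- row + 1L
        newpop[row, ] <- child
      }
    }
    pop <- newpop
    fit <- score_pop(pop)
    if (min(fit) < best_fit) {
      best_fit <- min(fit)
      best_chrom <- pop[which.min(fit), ]
    }
    trace <- c(trace, best_fit)
  }
  structure(list(selected_columns = colnames(X)[best_chrom],
                 score_trace = trace, best_score = best_fit,
                 n_evaluations = n_eval),
            class = "selection_result")
}

#' Serialize a selection result to JSON
#'
#' @param result A `selection_result`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
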