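# Independent oracles and shared fixtures. Oracles are deliberately written
# from scratch (including their own copies of the rule tables) so they check
# the implementation rather than mirror it.

# -- drug-likeness: brute-force rule recount ---------------------------------

oracle_rule_tables <- list(
  DLS_01 = list(c("mw", -Inf, 500), c("mlogp", -Inf, 4.15),
                c("hbd", -Inf, 5), c("hba", -Inf, 10)),
  DLS_02 = list(c("hbd", -Inf, 5), c("hba", 1, 8), c("mw", 200, 450),
                c("mlogp", -2.0, 4.5), c("rbn", 1, 9), c("n_rings", -Inf, 5)),
  DLS_03 = list(c("hbd", -Inf, 5), c("hba", -Inf, 10), c("mw", 200, 500),
                c("mlogp", -5, 5), c("rbn", -Inf, 8),
                c("formal_charge", -2, 2)),
  DLS_04 = list(c("hbd", -Inf, 5), c("hba", 2, 10), c("mw", 78, 500),
                c("mlogp", -0.5, 5.0), c("csp3_ratio", 0.15, 0.8),
                c("h_ratio", 0.6, 1.6), c("unsat_p", 0.10, 0.45)),
  DLS_05 = list(c("no_to_csp3", 0.10, 1.80), c("unsat_p", -Inf, 0.43)),
  DLS_06 = list(c("hbd", -Inf, 5), c("hba", -Inf, 10), c("mw", -Inf, 500),
                c("mlogp", -Inf, 5), c("rbn", -Inf, 10),
                c("tpsa", -Inf, 140)),
  DLS_07 = list(c("rbn", -Inf, 10), c("tpsa", -Inf, 140)))

oracle_dls_one <- function(profile, rules) {
  n_ok <- 0L
  for (r in rules) {
    v <- as.numeric(profile[[r[1]]])
    lo <- as.numeric(r[2]); hi <- as.numeric(r[3])
    if (!is.na(v) && v >= lo && v <= hi) n_ok <- n_ok + 1L
  }
  n_ok / length(rules)
}

oracle_dls_all <- function(profile) {
  s <- vapply(oracle_rule_tables, oracle_dls_one, numeric(1),
              profile = profile)
  c(s, DLS_cons = mean(s))
}

# wide random profiles (occasionally with undefined no_to_csp3)
random_profiles <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    id = sprintf("r%04d", seq_len(n)),
    mw = runif(n, 20, 900), mlogp = runif(n, -8, 9),
    hba = sample(0:16, n, TRUE), hbd = sample(0:9, n, TRUE),
    rbn = sample(0:16, n, TRUE), tpsa = runif(n, 0, 260),
    n_rings = sample(0:9, n, TRUE), formal_charge = sample(-3:3, n, TRUE),
    csp3_ratio = runif(n, 0, 1), h_ratio = runif(n, 0, 2.6),
    no_to_csp3 = runif(n, 0, 3), unsat_p = runif(n, 0, 1))
  df$no_to_csp3[sample(n, max(1, n %/% 50))] <- NA  # Csp3-free compounds
  df
}

# -- correlation filter: literal restatement of the removal rule -------------

oracle_corr_filter <- function(m, threshold) {
  cols <- colnames(m)
  repeat {
    if (length(cols) < 2) break
    C <- abs(cor(m[, cols, drop = FALSE]))
    diag(C) <- 0
    if (max(C) <= threshold) break
    hit <- which(C == max(C), arr.ind = TRUE)[1, ]
    a <- cols[hit[1]]; b <- cols[hit[2]]
    mean_a <- mean(C[hit[1], -hit[1]])
    mean_b <- mean(C[hit[2], -hit[2]])
    victim <- if (mean_a > mean_b) a
              else if (mean_b > mean_a) b
              else cols[max(match(c(a, b), colnames(m)))]
    # tie rule compares input order, but removal order here tracks `cols`
    if (mean_a == mean_b) {
      victim <- c(a, b)[which.max(match(c(a, b), colnames(m)))]
    }
    cols <- setdiff(cols, victim)
  }
  cols
}

# -- shared small trained bundle (expensive; built once per test run) --------

.fixture_env <- new.env(parent = emptyenv())

tiny_bundle <- function() {
  if (!is.null(.fixture_env$bundle)) return(.fixture_env$bundle)
  d <- generate_qspr_dataset(synthetic_spec(
    n_compounds = 250, n_informative = 4, n_redundant = 3, n_noise = 15,
    n_near_constant = 1, missing_fraction = 0.01, noise_sd = 0.35,
    seed = 42))
  cfg <- run_config(
    rfe = rfe_config(subset_sizes = 1:8, cv_folds = 5, cv_repeats = 1,
                     ranker_trees = 60),
    ga = ga_config(max_generations = 4, population_size = 10,
                   fitness_trees = 60),
    cv = cv_config(folds = 5, repeats = 1), seed = 99, verbose = FALSE)
  .fixture_env$bundle <- list(data = d, config = cfg,
                              bundle = run_training(d$matrix, d$response, cfg))
  .fixture_env$bundle
}
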