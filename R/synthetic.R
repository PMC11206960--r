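#' Specification for a synthetic QSPR dataset
#'
#' Defines the statistical structure of a simulated compounds x descriptors
#' matrix and its log Papp response. Columns come in four planted kinds:
#' informative (independent standard normals that drive the response),
#' redundant (affine copies of informative or noise columns plus small jitter,
#' pairwise |r| > 0.95 with their source), pure noise, and near-constant
#' (one value on >= 99% of rows). The response is a fixed smooth nonlinear
#' function of the informative columns -- a weighted sum plus one pairwise
#' interaction and one centered quadratic term -- calibrated so its noiseless
#' part has the requested mean and spans the requested range, plus Gaussian
#' noise. Defaults mirror the log Papp summary statistics of the Caco-2
#' modelling set this pipeline targets (mean -5.34, range [-7.70, -3.78]).
#'
#' @param n_compounds Number of rows (compounds).
#' @param n_informative Number of response-driving columns (>= 1 when a
#'   response is generated).
#' @param n_redundant Number of near-duplicate columns; each is an affine
#'   transform of a randomly chosen informative or noise column plus jitter
#'   with sd = 0.05 x source sd.
#' @param n_noise Number of independent standard-normal nuisance columns.
#' @param n_near_constant Number of columns constant on >= 99% of rows.
#' @param missing_fraction Fraction of descriptor cells set missing
#'   completely at random, in [0, 1); the response never has missings.
#' @param noise_sd Standard deviation of the Gaussian response noise
#'   (log Papp units).
#' @param response_mean Target mean of the noiseless response component.
#' @param response_range Length-2 numeric, target (min, max) of the noiseless
#'   response component.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 800, n_informative = 5,
                           n_redundant = 10, n_noise = 85,
                           n_near_constant = 2, missing_fraction = 0.02,
                           noise_sd = 0.4, response_mean = -5.34,
                           response_range = c(-7.70, -3.78), seed = 1) {
  spec <- list(n_compounds = as.integer(n_compounds),
               n_informative = as.integer(n_informative),
               n_redundant = as.integer(n_redundant),
               n_noise = as.integer(n_noise),
               n_near_constant = as.integer(n_near_constant),
               missing_fraction = missing_fraction,
               noise_sd = noise_sd,
               response_mean = response_mean,
               response_range = as.numeric(response_range),
               seed = as.integer(seed))
  if (spec$n_compounds < 1) stop("n_compounds must be >= 1", call. = FALSE)
  counts <- c(spec$n_informative, spec$n_redundant, spec$n_noise,
              spec$n_near_constant)
  if (any(counts < 0)) stop("column counts must be >= 0", call. = FALSE)
  if (spec$missing_fraction < 0 || spec$missing_fraction >= 1) {
    stop("missing_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(spec$response_range) != 2 ||
      spec$response_range[1] >= spec$response_range[2]) {
    stop("response_range must be (min, max) with min < max", call. = FALSE)
  }
  class(spec) <- "synthetic_spec"
  spec
}

# Fixed smooth nonlinear map from the informative block Z (n x k) to the
# unscaled response: weighted linear terms, one pairwise product (k >= 2) and
# one centered quadratic (non-monotone) term in the last column.
true_response_function <- function(Z) {
  k <- ncol(Z)
  w <- rep_len(c(1.0, 0.8, 0.9), k)
  f <- as.numeric(Z %*% w)
  if (k >= 2) f <- f + 1.2 * Z[, k - 1] * Z[, k]
  f <- f - 1.0 * (Z[, k]^2 - 1)
  f
}

# Continuous two-piece linear calibration with knot at mean(x): sends min(x)
# to lo and max(x) to hi exactly, and solves for the knot image c (the
# transformed values are linear in c) so the transformed mean equals `mid`
# exactly. Monotone whenever lo <= c <= hi, which holds for moderate skew.
piecewise_rescale <- function(x, lo, mid, hi) {
  mn <- min(x); mx <- max(x); mu <- mean(x)
  if (mx - mn < .Machine$double.eps) return(rep(mid, length(x)))
  t <- pmax(0, pmin(1, (x - mn) / (mu - mn)))  # position within lower branch
  s <- pmax(0, pmin(1, (x - mu) / (mx - mu)))  # position within upper branch
  lower <- x <= mu
  # g_i = lo + t_i (c - lo) on the lower branch, c + s_i (hi - c) above;
  # mean(g) = const + slope * c, solve for c
  const <- (sum(lo * (1 - t[lower])) + sum(s[!lower] * hi)) / length(x)
  slope <- (sum(t[lower]) + sum(1 - s[!lower])) / length(x)
  cc <- (mid - const) / slope
  out <- numeric(length(x))
  out[lower] <- lo + t[lower] * (cc - lo)
  out[!lower] <- cc + s[!lower] * (hi - cc)
  out
}

#' Generate a synthetic descriptor matrix with a log Papp response
#'
#' Draws the dataset described by a [synthetic_spec()]: a descriptor matrix
#' whose columns are (in shuffled order) informative, redundant,
#' near-constant and noise, a response vector, and a ground-truth record for
#' parameter-recovery tests.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements:
#'   * `matrix`: descriptor matrix (`n_compounds` rows, one column per
#'     planted descriptor), with `NA`s at the requested missing fraction;
#'   * `response`: numeric log Papp vector (no missings);
#'   * `truth`: list with `informative_columns`, `redundant_map`
#'     (named character vector redundant -> source), `near_constant_columns`,
#'     `noise_columns`, `noiseless` (the calibrated noise-free response
#'     component), `realized_noise_sd`, and `true_function` (description).
#' @export
generate_qspr_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_informative < 1) {
    stop("n_informative must be >= 1 to generate a response", call. = FALSE)
  }
  n <- spec$n_compounds
  set.seed(spec$seed)

  Z <- matrix(stats::rnorm(n * spec$n_informative), n)
  Nz <- matrix(stats::rnorm(n * spec$n_noise), n,
               ncol = spec$n_noise)
  blocks <- list(informative = Z, noise = Nz)
  kinds <- c(rep("informative", spec$n_informative),
             rep("noise", spec$n_noise))
  X <- cbind(Z, Nz)

  # redundant columns: affine copies (random slope/offset) + 5% jitter
  src_pool <- seq_len(ncol(X))
  red_src <- if (spec$n_redundant > 0) {
    sample(src_pool, spec$n_redundant, replace = spec$n_redundant > length(src_pool))
  } else integer(0)
  R <- matrix(0, n, spec$n_redundant)
  for (j in seq_len(spec$n_redundant)) {
    s <- X[, red_src[j]]
    a <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 2)
    b <- stats::runif(1, -1, 1)
    R[, j] <- a * (s + stats::rnorm(n, 0, 0.05 * stats::sd(s))) + b
  }

  # near-constant columns: one value everywhere except < 1% flipped rows
  C <- matrix(0, n, spec$n_near_constant)
  for (j in seq_len(spec$n_near_constant)) {
    v <- stats::runif(1, -2, 2)
    C[, j] <- v
    n_flip <- max(1L, floor(0.005 * n))
    if (n > 1) C[sample(n, n_flip), j] <- v + stats::runif(1, 1, 2)
  }

  full <- cbind(X, R, C)
  kinds <- c(kinds, rep("redundant", spec$n_redundant),
             rep("near_constant", spec$n_near_constant))
  p <- ncol(full)
  ord <- sample(p)
  full <- full[, ord, drop = FALSE]
  kinds <- kinds[ord]
  colnames(full) <- sprintf("d%03d", seq_len(p))
  rownames(full) <- sprintf("cmp_%04d", seq_len(n))
  # position of each pre-shuffle column in the shuffled matrix
  newpos <- match(seq_len(p), ord)

  f <- true_response_function(Z)
  g <- piecewise_rescale(f, spec$response_range[1], spec$response_mean,
                         spec$response_range[2])
  eps <- stats::rnorm(n, 0, spec$noise_sd)
  y <- g + eps
  names(y) <- rownames(full)

  inf_names <- colnames(full)[newpos[seq_len(spec$n_informative)]]
  noise_names <- colnames(full)[newpos[spec$n_informative + seq_len(spec$n_noise)]]
  red_names <- colnames(full)[newpos[spec$n_informative + spec$n_noise +
                                       seq_len(spec$n_redundant)]]
  cst_names <- colnames(full)[newpos[spec$n_informative + spec$n_noise +
                                       spec$n_redundant +
                                       seq_len(spec$n_near_constant)]]
  red_map <- stats::setNames(colnames(full)[newpos[red_src]], red_names)

  if (spec$missing_fraction > 0 && p > 0) {
    n_miss <- floor(spec$missing_fraction * n * p)
    if (n_miss > 0) full[sample(n * p, n_miss)] <- NA_real_
  }

  list(matrix = as_descriptor_matrix(full),
       response = y,
       truth = list(
         informative_columns = inf_names,
         redundant_map = red_map,
         near_constant_columns = cst_names,
         noise_columns = noise_names,
         noiseless = stats::setNames(g, rownames(full)),
         realized_noise_sd = stats::sd(eps),
         true_function = paste(
           "weighted sum of informative columns + 1.2 * z[k-1]*z[k]",
           "- (z[k]^2 - 1), piecewise-linearly calibrated to the requested",
           "mean and range")))
}

# property columns used by the drug-likeness rule sets
property_columns <- c("mw", "mlogp", "hba", "hbd", "rbn", "tpsa", "n_rings",
                      "formal_charge", "csp3_ratio", "h_ratio", "no_to_csp3",
                      "unsat_p")

# sampling boxes per scenario: all_pass lies inside the intersection of every
# rule-set bound, all_fail violates every rule simultaneously, mixed straddles
# every threshold.
property_ranges <- list(
  all_pass = list(mw = c(200, 450), mlogp = c(-0.5, 4.15), hba = c(2, 8),
                  hbd = c(0, 5), rbn = c(1, 8), tpsa = c(20, 140),
                  n_rings = c(0, 5), formal_charge = c(-2, 2),
                  csp3_ratio = c(0.15, 0.8), h_ratio = c(0.6, 1.6),
                  no_to_csp3 = c(0.10, 1.80), unsat_p = c(0.10, 0.43)),
  all_fail = list(mw = c(550, 900), mlogp = c(5.5, 8), hba = c(11, 15),
                  hbd = c(6, 10), rbn = c(11, 15), tpsa = c(145, 250),
                  n_rings = c(6, 9), formal_charge = c(3, 5),
                  csp3_ratio = c(0.85, 1.0), h_ratio = c(1.7, 2.5),
                  no_to_csp3 = c(2.0, 3.0), unsat_p = c(0.5, 0.9)),
  mixed    = list(mw = c(50, 700), mlogp = c(-6, 7), hba = c(0, 14),
                  hbd = c(0, 8), rbn = c(0, 14), tpsa = c(0, 200),
                  n_rings = c(0, 8), formal_charge = c(-3, 3),
                  csp3_ratio = c(0, 1), h_ratio = c(0, 2.5),
                  no_to_csp3 = c(0, 2.5), unsat_p = c(0, 0.9))
)

#' Generate a synthetic molecular-property table
#'
#' Produces physicochemical-property profiles for exercising the
#' drug-likeness rule sets. `"all_pass"` profiles satisfy every rule of every
#' built-in rule set; `"all_fail"` profiles violate every rule (all rules can
#' be violated simultaneously); `"mixed"` profiles are drawn uniformly from
#' ranges straddling each rule threshold.
#'
#' @param n Number of profiles (>= 1).
#' @param scenario One of `"all_pass"`, `"all_fail"`, `"mixed"`.
#' @param seed Integer seed.
#' @return Data frame with an `id` column and the twelve property columns
#'   consumed by [dls_all()] (counts are integer-valued).
#' @export
generate_property_table <- function(n, scenario = c("all_pass", "all_fail",
                                                    "mixed"), seed = 1) {
  scenario <- match.arg(scenario)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  rng <- property_ranges[[scenario]]
  set.seed(as.integer(seed))
  out <- data.frame(id = sprintf("np_%04d", seq_len(n)))
  count_props <- c("hba", "hbd", "rbn", "n_rings", "formal_charge")
  for (p in property_columns) {
    r <- rng[[p]]
    if (p %in% count_props) {
      out[[p]] <- sample(seq(r[1], r[2]), n, replace = TRUE)
    } else {
      out[[p]] <- stats::runif(n, r[1], r[2])
    }
  }
  out
}
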