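#' The seven built-in drug-likeness rule sets
#'
#' Each rule set is a table of inclusive property bounds; a compound's
#' drug-likeness score for the set (see [dls_score()]) is the fraction of
#' rules it satisfies. The sets, in order:
#' * `DLS_01` (4 rules): Lipinski-style bounds with the Moriguchi logP form
#'   -- MW <= 500, MlogP <= 4.15, HBD <= 5, HBA <= 10;
#' * `DLS_02` (6 rules): HBD <= 5, HBA 1-8, MW 200-450, MlogP -2.0-4.5,
#'   RBN 1-9, rings <= 5;
#' * `DLS_03` (6 rules): HBD <= 5, HBA <= 10, MW 200-500, MlogP -5-5,
#'   RBN <= 8, formal charge -2-2;
#' * `DLS_04` (7 rules): HBD <= 5, HBA 2-10, MW 78-500, MlogP -0.5-5.0,
#'   Csp3 ratio 0.15-0.8, H ratio 0.6-1.6, Unsat-p 0.10-0.45;
#' * `DLS_05` (2 rules): (N+O)/Csp3 ratio 0.10-1.80, Unsat-p <= 0.43;
#' * `DLS_06` (6 rules): HBD <= 5, HBA <= 10, MW <= 500, MlogP <= 5,
#'   RBN <= 10, TPSA <= 140;
#' * `DLS_07` (2 rules): RBN <= 10, TPSA <= 140 (the Veber criteria).
#'
#' @return Named list of seven data frames with columns `property`, `lower`,
#'   `upper` (`NA` = unbounded on that side).
#' @export
builtin_rulesets <- function() {
  rule <- function(property, lower = NA_real_, upper = NA_real_) {
    data.frame(property = property, lower = lower, upper = upper,
               stringsAsFactors = FALSE)
  }
  list(
    DLS_01 = rbind(rule("mw", upper = 500), rule("mlogp", upper = 4.15),
                   rule("hbd", upper = 5), rule("hba", upper = 10)),
    DLS_02 = rbind(rule("hbd", upper = 5), rule("hba", 1, 8),
                   rule("mw", 200, 450), rule("mlogp", -2.0, 4.5),
                   rule("rbn", 1, 9), rule("n_rings", upper = 5)),
    DLS_03 = rbind(rule("hbd", upper = 5), rule("hba", upper = 10),
                   rule("mw", 200, 500), rule("mlogp", -5, 5),
                   rule("rbn", upper = 8), rule("formal_charge", -2, 2)),
    DLS_04 = rbind(rule("hbd", upper = 5), rule("hba", 2, 10),
                   rule("mw", 78, 500), rule("mlogp", -0.5, 5.0),
                   rule("csp3_ratio", 0.15, 0.8), rule("h_ratio", 0.6, 1.6),
                   rule("unsat_p", 0.10, 0.45)),
    DLS_05 = rbind(rule("no_to_csp3", 0.10, 1.80),
                   rule("unsat_p", upper = 0.43)),
    DLS_06 = rbind(rule("hbd", upper = 5), rule("hba", upper = 10),
                   rule("mw", upper = 500), rule("mlogp", upper = 5),
                   rule("rbn", upper = 10), rule("tpsa", upper = 140)),
    DLS_07 = rbind(rule("rbn", upper = 10), rule("tpsa", upper = 140)))
}

#' Load custom rule sets from JSON
#'
#' The JSON document maps rule-set names to arrays of
#' `{property, lower, upper}` objects; omitted bounds are unbounded.
#'
#' @param path JSON file path.
#' @return Named list of rule-set data frames as in [builtin_rulesets()].
#' @export
read_rulesets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(rules) {
    do.call(rbind, lapply(rules, function(r) {
      data.frame(property = r$property,
                 lower = if (is.null(r$lower)) NA_real_ else r$lower,
                 upper = if (is.null(r$upper)) NA_real_ else r$upper,
                 stringsAsFactors = FALSE)
    }))
  })
}

# value of property `p` from a one-row profile (data frame, list or named
# vector); error if absent
profile_value <- function(profile, p) {
  if (!p %in% names(profile)) {
    stop("profile lacks required property '", p, "'", call. = FALSE)
  }
  as.numeric(profile[[p]][1])
}

#' Drug-likeness score for one rule set
#'
#' The score is nRules/tRules: the fraction of the set's inclusive bounds
#' containing the compound's property values. An undefined property value
#' (`NA`, e.g. the (N+O)/Csp3 ratio of a compound without sp3 carbons)
#' counts as a violated rule.
#'
#' @param profile Named list, one-row data frame, or named vector of
#'   physicochemical properties.
#' @param ruleset One rule-set data frame (see [builtin_rulesets()]).
#' @return Score in [0, 1].
#' @export
dls_score <- function(profile, ruleset) {
  stopifnot(is.data.frame(ruleset), nrow(ruleset) >= 1)
  ok <- vapply(seq_len(nrow(ruleset)), function(i) {
    v <- profile_value(profile, ruleset$property[i])
    if (is.na(v)) return(FALSE)
    (is.na(ruleset$lower[i]) || v >= ruleset$lower[i]) &&
      (is.na(ruleset$upper[i]) || v <= ruleset$upper[i])
  }, logical(1))
  sum(ok) / nrow(ruleset)
}

#' All eight drug-likeness scores for one compound
#'
#' Scores the profile against the seven built-in rule sets and adds the
#' consensus score `DLS_cons`, the arithmetic mean of the seven.
#'
#' @inheritParams dls_score
#' @param rulesets Named list of rule sets (default [builtin_rulesets()]).
#' @return Named numeric vector: one score per rule set plus `DLS_cons`.
#' @export
dls_all <- function(profile, rulesets = builtin_rulesets()) {
  scores <- vapply(rulesets, dls_score, numeric(1), profile = profile)
  c(scores, DLS_cons = mean(scores))
}

#' Drug-likeness scores for a property table
#'
#' @param profiles Data frame of property profiles (one row per compound).
#' @param rulesets Named list of rule sets.
#' @return Data frame of scores, one row per profile, columns as [dls_all()].
#' @export
dls_table <- function(profiles, rulesets = builtin_rulesets()) {
  out <- t(vapply(seq_len(nrow(profiles)),
                  function(i) dls_all(profiles[i, , drop = FALSE], rulesets),
                  numeric(length(rulesets) + 1)))
  as.data.frame(out)
}

#' Lipinski rule-of-five compliance
#'
#' Checks MW <= 500, MlogP <= 4.15, HBD <= 5, HBA <= 10 (the Moriguchi-logP
#' form of the rule; bounds inclusive). A compound is compliant when at most
#' `max_violations` rules fail (default 0).
#'
#' @inheritParams dls_score
#' @param max_violations Violations tolerated while still compliant
#'   (default 0).
#' @return List with `compliant` flag and `violations` (character vector of
#'   failed properties).
#' @export
ro5_compliant <- function(profile, max_violations = 0) {
  rules <- builtin_rulesets()$DLS_01
  bad <- rules$property[vapply(seq_len(nrow(rules)), function(i) {
    v <- profile_value(profile, rules$property[i])
    is.na(v) || v > rules$upper[i]
  }, logical(1))]
  list(compliant = length(bad) <= max_violations, violations = bad)
}

#' Veber-criteria compliance (RBN <= 10 and TPSA <= 140)
#'
#' @inheritParams dls_score
#' @return List with `compliant` flag and `violations`.
#' @export
veber_compliant <- function(profile) {
  bad <- character(0)
  if (profile_value(profile, "rbn") > 10) bad <- c(bad, "rbn")
  if (profile_value(profile, "tpsa") > 140) bad <- c(bad, "tpsa")
  list(compliant = length(bad) == 0, violations = bad)
}

#' Permeability class from log Papp
#'
#' high: log Papp > -5 (suggesting high intestinal absorption);
#' medium: -6 <= log Papp <= -5; low: log Papp < -6. The boundaries -5 and
#' -6 map to medium.
#'
#' @param log_papp Finite numeric vector of log10 apparent permeabilities.
#' @return Factor with levels `high`, `medium`, `low`.
#' @export
classify_permeability <- function(log_papp) {
  if (any(!is.finite(log_papp))) stop("log_papp must be finite", call. = FALSE)
  factor(ifelse(log_papp > -5, "high",
                ifelse(log_papp < -6, "low", "medium")),
         levels = c("high", "medium", "low"))
}

#' Class counts and percentages for a set of predictions
#'
#' @param log_papp Non-empty finite numeric vector.
#' @return Data frame with `class`, `n`, `percent` (percent of the input,
#'   rounded to one decimal).
#' @export
summarize_classes <- function(log_papp) {
  if (!length(log_papp)) stop("empty input", call. = FALSE)
  cls <- classify_permeability(log_papp)
  tab <- table(cls)
  data.frame(class = names(tab), n = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(cls), 1),
             stringsAsFactors = FALSE)
}
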