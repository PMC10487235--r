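#' Linguistic variables of the riboflavin fermentation model
#'
#' The five variables of the semi-defined-medium model: four inputs —
#' casamino acid (5-20 g/L, peaks 5 / 12.5 / 20), GTP (0.01-0.04 g/L, peaks
#' 0.01 / 0.025 / 0.04), sodium acetate (5-15 g/L, peaks 5 / 10 / 15),
#' glycine (5-15 g/L, peaks 5 / 10 / 15) — and the riboflavin output
#' (340-440 ug/L, peaks 340 / 390 / 440). Each is a three-term
#' low/medium/high variable built with [three_term_variable()], so the
#' extreme terms are shoulders anchored at the universe edges and the three
#' memberships sum to 1 everywhere.
#'
#' @return Named list of `fuzzy_variable`s:
#'   `casamino`, `gtp`, `sodium_acetate`, `glycine`, `riboflavin`.
#' @examples
#' cat <- riboflavin_variables()
#' fuzzify(cat$casamino, 8.75)
#' @export
riboflavin_variables <- function() {
  list(
    casamino       = three_term_variable("casamino", 5, 12.5, 20),
    gtp            = three_term_variable("gtp", 0.01, 0.025, 0.04),
    sodium_acetate = three_term_variable("sodium_acetate", 5, 10, 15),
    glycine        = three_term_variable("glycine", 5, 10, 15),
    riboflavin     = three_term_variable("riboflavin", 340, 390, 440)
  )
}

#' Medium-component factor names
#' @return Character vector of the four input factor names.
#' @export
riboflavin_factors <- function() {
  c("casamino", "gtp", "sodium_acetate", "glycine")
}

#' Baseline (low-peak) levels of the four factors
#'
#' In OFAT experiments the off-study factors are held at their baseline,
#' taken here as each variable's low-term peak (the universe floor).
#'
#' @return Named numeric vector, one level per factor (g/L).
#' @export
baseline_levels <- function() {
  cat <- riboflavin_variables()
  vapply(riboflavin_factors(), function(f) cat[[f]]$universe[1], numeric(1))
}

#' Single-factor riboflavin prediction model
#'
#' Builds a one-input Mamdani model mapping one medium component to
#' riboflavin, the form used when each OFAT dose-response series is
#' modelled on its own. All rules must reference only that factor.
#'
#' @param factor One of `riboflavin_factors()`.
#' @param rules List of `fuzzy_rule`s (or an `induced_rulebase`) whose
#'   antecedents mention only `factor`.
#' @param grid_points Output discretization, default 1001.
#' @return A `mamdani_model`.
#' @export
build_single_factor_model <- function(factor, rules, grid_points = 1001L) {
  cat <- riboflavin_variables()
  if (!is.character(factor) || length(factor) != 1L ||
      !factor %in% riboflavin_factors()) {
    stop(sprintf("unknown factor '%s'; expected one of %s",
                 paste(factor, collapse = ","),
                 paste(riboflavin_factors(), collapse = ", ")), call. = FALSE)
  }
  rules <- as_rule_list(rules)
  if (length(rules) == 0L) {
    stop("empty rule base", call. = FALSE)
  }
  for (r in rules) {
    extra <- setdiff(names(r$antecedent), factor)
    if (length(extra) > 0L) {
      stop(sprintf("rule references variable(s) %s, not the model factor '%s'",
                   paste(sQuote(extra), collapse = ", "), factor), call. = FALSE)
    }
  }
  mamdani_model(inputs = list(cat[[factor]]), output = cat$riboflavin,
                rules = rules, grid_points = grid_points)
}

#' Joint four-input riboflavin prediction model
#'
#' Builds the full model over all four medium components. Rules may
#' constrain any subset of the inputs; per-factor behaviour is recovered by
#' fixing the other three inputs at their [baseline_levels()] — variables a
#' rule does not mention cannot change its firing strength, so a joint
#' model whose rules only constrain one factor agrees exactly with the
#' corresponding single-factor model.
#'
#' @param rules List of `fuzzy_rule`s (or an `induced_rulebase`).
#' @param grid_points Output discretization, default 1001.
#' @return A `mamdani_model` with four inputs.
#' @export
build_joint_model <- function(rules, grid_points = 1001L) {
  cat <- riboflavin_variables()
  rules <- as_rule_list(rules)
  if (length(rules) == 0L) {
    stop("empty rule base", call. = FALSE)
  }
  mamdani_model(inputs = cat[riboflavin_factors()], output = cat$riboflavin,
                rules = rules, grid_points = grid_points)
}

as_rule_list <- function(rules) {
  if (inherits(rules, "induced_rulebase")) return(rules$rules)
  if (inherits(rules, "fuzzy_rule")) return(list(rules))
  stopifnot(is.list(rules))
  rules
}
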