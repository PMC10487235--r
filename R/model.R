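#' Fuzzy if-then rule
#'
#' One Mamdani rule: IF each antecedent variable takes its named term
#' THEN the output takes the consequent term. Multiple antecedent entries
#' are combined with the model's AND operator (minimum). A weight in
#' `(0, 1]` scales the firing strength.
#'
#' @param antecedent Named character vector, `variable name -> term label`;
#'   at most one entry per variable.
#' @param consequent Output term label.
#' @param weight Rule weight in `(0, 1]`, default 1.
#' @return An object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedent, consequent, weight = 1) {
  stopifnot(is.character(antecedent), length(antecedent) >= 1L,
            is.character(consequent), length(consequent) == 1L,
            is.numeric(weight), length(weight) == 1L)
  if (is.null(names(antecedent)) || any(!nzchar(names(antecedent)))) {
    stop("rule antecedent must be a named character vector (variable -> term)",
         call. = FALSE)
  }
  if (anyDuplicated(names(antecedent))) {
    stop("rule antecedent mentions a variable more than once", call. = FALSE)
  }
  if (weight <= 0 || weight > 1) {
    stop("rule weight must lie in (0, 1]", call. = FALSE)
  }
  structure(list(antecedent = antecedent, consequent = consequent,
                 weight = weight),
            class = "fuzzy_rule")
}

#' Mamdani fuzzy inference model
#'
#' Assembles input variables, an output variable and a rule base into a
#' complete predictive model. Operators are the classical Mamdani triple —
#' minimum AND, minimum implication, maximum aggregation — with centroid
#' defuzzification; the operator record is stored so alternatives could be
#' added, but only these are currently implemented. The output universe is
#' discretized on `grid_points` equally spaced samples (the default 1001
#' gives 0.1 ug/L resolution on a 100 ug/L riboflavin universe).
#'
#' Construction fails if a rule references an unknown variable or term, or
#' if two rules share an identical antecedent with different consequents
#' (such conflicts must be resolved before building the model, e.g. by
#' [induce_rules()]).
#'
#' @param inputs List of input `fuzzy_variable`s.
#' @param output Output `fuzzy_variable`.
#' @param rules List of [fuzzy_rule()]s, at least one.
#' @param grid_points Positive integer (>= 2) output discretization.
#' @param operators Operator record; only the classical defaults are
#'   supported.
#' @return An object of class `mamdani_model`.
#' @export
mamdani_model <- function(inputs, output, rules, grid_points = 1001L,
                          operators = mamdani_operators()) {
  if (inherits(inputs, "fuzzy_variable")) inputs <- list(inputs)
  stopifnot(is.list(inputs), length(inputs) >= 1L,
            inherits(output, "fuzzy_variable"),
            is.list(rules),
            is.numeric(grid_points), length(grid_points) == 1L)
  grid_points <- as.integer(grid_points)
  if (is.na(grid_points) || grid_points < 2L) {
    stop("grid_points must be an integer >= 2", call. = FALSE)
  }
  if (inherits(rules, "fuzzy_rule")) rules <- list(rules)
  if (length(rules) < 1L) {
    stop("a Mamdani model needs at least one rule", call. = FALSE)
  }
  supported <- mamdani_operators()
  if (!identical(operators[names(supported)], supported)) {
    stop("only the classical Mamdani operators (min/min/max/centroid) are implemented",
         call. = FALSE)
  }
  for (v in inputs) stopifnot(inherits(v, "fuzzy_variable"))
  names(inputs) <- vapply(inputs, `[[`, character(1), "name")
  if (anyDuplicated(names(inputs))) {
    stop("duplicate input variable names", call. = FALSE)
  }
  if (output$name %in% names(inputs)) {
    stop("output variable shares a name with an input", call. = FALSE)
  }

  keys <- character(length(rules))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (!inherits(r, "fuzzy_rule")) stop("rules must be fuzzy_rule objects", call. = FALSE)
    for (vn in names(r$antecedent)) {
      if (!vn %in% names(inputs)) {
        stop(sprintf("rule %d references unknown input variable '%s'", i, vn),
             call. = FALSE)
      }
      if (!r$antecedent[[vn]] %in% names(inputs[[vn]]$terms)) {
        stop(sprintf("rule %d references unknown term '%s' of variable '%s'",
                     i, r$antecedent[[vn]], vn), call. = FALSE)
      }
    }
    if (!r$consequent %in% names(output$terms)) {
      stop(sprintf("rule %d references unknown output term '%s'", i, r$consequent),
           call. = FALSE)
    }
    ant <- r$antecedent[order(names(r$antecedent))]
    keys[i] <- paste(names(ant), ant, sep = "=", collapse = "&")
  }
  for (k in unique(keys)) {
    cons <- unique(vapply(rules[keys == k], `[[`, character(1), "consequent"))
    if (length(cons) > 1L) {
      stop(sprintf("conflicting rules: antecedent {%s} maps to consequents %s",
                   k, paste(cons, collapse = ", ")), call. = FALSE)
    }
  }

  structure(list(inputs = inputs, output = output, rules = rules,
                 operators = supported, grid_points = grid_points),
            class = "mamdani_model")
}

#' @rdname mamdani_model
#' @export
mamdani_operators <- function() {
  list(and = "min", implication = "min", aggregation = "max",
       defuzzifier = "centroid")
}

#' Firing strength of a rule
#'
#' Minimum, over the rule's antecedent entries, of the crisp input's
#' membership in the named term, scaled by the rule weight.
#'
#' @param rule A `fuzzy_rule`.
#' @param inputs Named list or vector of crisp input values.
#' @param model The `mamdani_model` supplying the variables.
#' @return Degree in `[0, 1]`.
#' @export
firing_strength <- function(rule, inputs, model) {
  stopifnot(inherits(rule, "fuzzy_rule"), inherits(model, "mamdani_model"))
  inputs <- as.list(inputs)
  degs <- numeric(length(rule$antecedent))
  for (i in seq_along(rule$antecedent)) {
    vn <- names(rule$antecedent)[i]
    if (is.null(inputs[[vn]])) {
      stop(sprintf("no input value supplied for antecedent variable '%s'", vn),
           call. = FALSE)
    }
    degs[i] <- fuzzify(model$inputs[[vn]], inputs[[vn]])[[rule$antecedent[[i]]]]
  }
  min(degs) * rule$weight
}

#' Run Mamdani inference
#'
#' Fuzzifies the inputs, fires every rule, clips each consequent membership
#' function at the rule's firing strength (minimum implication) and
#' aggregates the clipped sets pointwise by maximum over an equally spaced
#' grid spanning the output universe. If no rule attains positive strength
#' the prediction is undefined and a classed error
#' (`ribofis_no_rule_fired`) is raised — a silent zero surface would leave
#' the output universe and corrupt downstream validation.
#'
#' @inheritParams firing_strength
#' @param model A `mamdani_model`.
#' @return An `aggregated_output`: list with `grid` (ascending sample
#'   points) and `degrees` (membership at each point).
#' @export
infer <- function(model, inputs) {
  stopifnot(inherits(model, "mamdani_model"))
  u <- model$output$universe
  grid <- seq(u[1], u[2], length.out = model$grid_points)
  degrees <- numeric(model$grid_points)
  fired <- FALSE
  for (rule in model$rules) {
    s <- firing_strength(rule, inputs, model)
    if (s <= 0) next
    fired <- TRUE
    cons <- model$output$terms[[rule$consequent]]
    degrees <- pmax(degrees, pmin(s, mf_degree(cons, grid)))
  }
  if (!fired) {
    stop(errorCondition(
      "no rule fired for the supplied inputs; prediction undefined",
      class = c("ribofis_no_rule_fired", "error", "condition")
    ))
  }
  structure(list(grid = grid, degrees = degrees), class = "aggregated_output")
}

#' Centroid defuzzification
#'
#' Discrete centroid of an aggregated output surface:
#' `sum(grid * degrees) / sum(degrees)`. The result always lies between the
#' smallest and largest grid points carrying positive degree.
#'
#' @param agg An `aggregated_output` from [infer()].
#' @return Crisp output value (ug/L for the riboflavin model).
#' @export
defuzzify_centroid <- function(agg) {
  stopifnot(inherits(agg, "aggregated_output"))
  total <- sum(agg$degrees)
  if (total <= 0) {
    stop(errorCondition(
      "cannot defuzzify an all-zero surface",
      class = c("ribofis_no_rule_fired", "error", "condition")
    ))
  }
  sum(agg$grid * agg$degrees) / total
}

#' Predict riboflavin from crisp inputs
#'
#' Composition of [infer()] and [defuzzify_centroid()]. `newdata` may be a
#' named list/vector (one prediction) or a data frame with one column per
#' input variable (one prediction per row). Results always lie within the
#' output universe.
#'
#' @param object A `mamdani_model`.
#' @param newdata Named list/vector of crisp inputs, or a data frame.
#' @param ... Unused.
#' @return Numeric vector of crisp predictions.
#' @export
predict.mamdani_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    return(vapply(seq_len(nrow(newdata)), function(i) {
      defuzzify_centroid(infer(object, as.list(newdata[i, , drop = FALSE])))
    }, numeric(1)))
  }
  defuzzify_centroid(infer(object, newdata))
}

#' @export
print.mamdani_model <- function(x, ...) {
  cat(sprintf("Mamdani model: %d input(s) -> '%s', %d rule(s), %d grid points\n",
              length(x$inputs), x$output$name, length(x$rules), x$grid_points))
  for (r in x$rules) {
    cat(sprintf("  IF %s THEN %s is %s%s\n",
                paste(names(r$antecedent), "is", r$antecedent, collapse = " AND "),
                x$output$name, r$consequent,
                if (r$weight < 1) sprintf(" (weight %g)", r$weight) else ""))
  }
  invisible(x)
}
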