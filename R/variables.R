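#' Linguistic fuzzy variable
#'
#' A named input or output variable defined on a closed universe interval,
#' carrying an ordered set of linguistic terms (e.g. low / medium / high),
#' each a triangular membership function. Validation enforces: the universe
#' is a proper interval; every term's support lies inside it; term peaks
#' strictly increase with term order; and coverage — every point of the
#' universe has positive membership in at least one term.
#'
#' @param name Variable identifier (e.g. `"casamino"`).
#' @param universe Numeric length-2 vector `c(umin, umax)`, `umin < umax`.
#'   Units are g/L for medium components, ug/L for riboflavin.
#' @param terms Named list of [trimf()] objects, in linguistic order; names
#'   are the term labels and must be unique.
#' @return An object of class `fuzzy_variable`.
#' @seealso [three_term_variable()] for the peak-anchored low/medium/high
#'   construction used throughout the riboflavin model.
#' @export
fuzzy_variable <- function(name, universe, terms) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(universe), length(universe) == 2L,
            is.list(terms), length(terms) >= 1L)
  if (!(universe[1] < universe[2])) {
    stop(sprintf("variable '%s': universe must satisfy umin < umax", name),
         call. = FALSE)
  }
  labels <- names(terms)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop(sprintf("variable '%s': terms must have unique non-empty labels", name),
         call. = FALSE)
  }
  for (lab in labels) {
    mf <- terms[[lab]]
    if (!inherits(mf, "trimf")) {
      stop(sprintf("variable '%s': term '%s' is not a trimf", name, lab),
           call. = FALSE)
    }
    if (mf$a < universe[1] || mf$c > universe[2]) {
      stop(sprintf("variable '%s': support of term '%s' exceeds universe [%g, %g]",
                   name, lab, universe[1], universe[2]), call. = FALSE)
    }
  }
  peaks <- vapply(terms, function(mf) mf$b, numeric(1))
  if (length(peaks) > 1L && any(diff(peaks) <= 0)) {
    stop(sprintf("variable '%s': term peaks must strictly increase with term order",
                 name), call. = FALSE)
  }
  var <- structure(
    list(name = name, universe = as.numeric(universe), terms = terms),
    class = "fuzzy_variable"
  )
  grid <- seq(universe[1], universe[2], length.out = 257L)
  cover <- Reduce(pmax, lapply(terms, mf_degree, x = grid))
  if (any(cover <= 0)) {
    stop(sprintf("variable '%s': terms do not cover the universe (gap near %g)",
                 name, grid[which(cover <= 0)[1]]), call. = FALSE)
  }
  var
}

#' Three-term peak-anchored variable
#'
#' Builds a low/medium/high variable on `[umin, umax]` from the three term
#' peaks: low is the left-shoulder triangle `(umin, umin, mid)`, medium the
#' full triangle `(umin, mid, umax)`, high the right-shoulder
#' `(mid, umax, umax)`. Adjacent terms share feet at each other's peaks, so
#' the three memberships form a partition of unity (sum to 1 everywhere on
#' the universe) and coverage holds at the boundaries.
#'
#' @param name Variable identifier.
#' @param umin,mid,umax Peaks of low, medium and high; `umin < mid < umax`.
#' @param labels Term labels, default `c("low", "medium", "high")`.
#' @return A `fuzzy_variable`.
#' @export
three_term_variable <- function(name, umin, mid, umax,
                                labels = c("low", "medium", "high")) {
  stopifnot(length(labels) == 3L)
  if (!(umin < mid && mid < umax)) {
    stop(sprintf("variable '%s': need umin < mid < umax, got (%g, %g, %g)",
                 name, umin, mid, umax), call. = FALSE)
  }
  terms <- list(trimf(umin, umin, mid), trimf(umin, mid, umax),
                trimf(mid, umax, umax))
  names(terms) <- labels
  fuzzy_variable(name, c(umin, umax), terms)
}

#' Fuzzify a crisp value
#'
#' Maps a crisp value to its vector of term membership degrees. The value
#' must lie inside the variable's universe: the model is only defined there,
#' so out-of-range inputs are rejected rather than clamped.
#'
#' @param variable A `fuzzy_variable`.
#' @param x Scalar universe value.
#' @return Named numeric vector of degrees, one per term, in term order.
#' @export
fuzzify <- function(variable, x) {
  stopifnot(inherits(variable, "fuzzy_variable"),
            is.numeric(x), length(x) == 1L, is.finite(x))
  u <- variable$universe
  if (x < u[1] || x > u[2]) {
    stop(errorCondition(
      sprintf("value %g is outside the universe [%g, %g] of variable '%s'",
              x, u[1], u[2], variable$name),
      class = c("ribofis_out_of_range", "error", "condition")
    ))
  }
  vapply(variable$terms, mf_degree, numeric(1), x = x)
}

#' @export
print.fuzzy_variable <- function(x, ...) {
  cat(sprintf("fuzzy variable '%s' on [%g, %g], %d terms:\n",
              x$name, x$universe[1], x$universe[2], length(x$terms)))
  for (lab in names(x$terms)) {
    mf <- x$terms[[lab]]
    cat(sprintf("  %-10s (%g, %g, %g)\n", lab, mf$a, mf$b, mf$c))
  }
  invisible(x)
}
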