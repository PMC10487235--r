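#' Triangular membership function
#'
#' Constructs a triangular fuzzy membership function from its three abscissae:
#' left foot `a`, peak `b`, right foot `c`. Degenerate shoulders are legal:
#' `a == b` gives a left-shoulder (rising edge collapsed, degree 1 at the
#' peak and falling to the right), `b == c` a right-shoulder. Zero-width
#' functions (`a == c`) are rejected because they carry no support.
#'
#' @param a Left foot, in universe units.
#' @param b Peak; membership equals 1 exactly here.
#' @param c Right foot.
#' @return An object of class `trimf`.
#' @examples
#' mf <- trimf(5, 12.5, 20)
#' mf_degree(mf, c(5, 8.75, 12.5, 20, 21))
#' @export
trimf <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1L, length(b) == 1L, length(c) == 1L)
  if (!is.finite(a) || !is.finite(b) || !is.finite(c)) {
    stop("triangular membership abscissae must be finite", call. = FALSE)
  }
  if (!(a <= b && b <= c)) {
    stop(sprintf("invalid triangular geometry: need a <= b <= c, got (%g, %g, %g)",
                 a, b, c), call. = FALSE)
  }
  if (a == c) {
    stop(sprintf("zero-width triangular membership function at %g rejected", a),
         call. = FALSE)
  }
  structure(list(a = a, b = b, c = c), class = "trimf")
}

#' Membership degree of a triangular function
#'
#' Evaluates `max(0, min((x - a)/(b - a), (c - x)/(c - b)))`, with the
#' convention that a collapsed edge (`a == b` or `b == c`) contributes
#' degree 1 on its side of the peak, so shoulders evaluate to 1 at `b`.
#' Total over all real `x`; returns 0 outside the support `[a, c]`.
#'
#' @param mf A [trimf()] object.
#' @param x Numeric vector of universe values.
#' @return Numeric vector of degrees in `[0, 1]`.
#' @export
mf_degree <- function(mf, x) {
  stopifnot(inherits(mf, "trimf"), is.numeric(x))
  up <- if (mf$b > mf$a) (x - mf$a) / (mf$b - mf$a) else as.numeric(x >= mf$b)
  dn <- if (mf$c > mf$b) (mf$c - x) / (mf$c - mf$b) else as.numeric(x <= mf$b)
  pmax(0, pmin(up, dn, 1))
}

#' @export
print.trimf <- function(x, ...) {
  cat(sprintf("triangular membership function: feet (%g, %g), peak %g\n",
              x$a, x$c, x$b))
  invisible(x)
}
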