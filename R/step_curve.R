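#' Right-continuous step curves
#'
#' All estimated curves (Kaplan-Meier survival, cumulative incidence,
#' current cumulative incidence, current leukaemia-free survival, state
#' occupation probabilities) are right-continuous piecewise-constant
#' functions. They are stored as tibbles with one row per jump: a `time`
#' column of strictly increasing jump times and an `estimate` column holding
#' the value attained at (and right of) each jump. The value before the
#' first jump is kept in the `origin` attribute. Evaluation beyond the last
#' jump returns the last value.
#'
#' @param time Strictly increasing, non-negative jump times.
#' @param estimate Curve value attained at each jump time.
#' @param origin Value of the curve on `[0, time[1])`.
#'
#' @return A tibble of class `step_curve` with columns `time` and `estimate`.
#' @examples
#' km <- step_curve(c(1, 2), c(0.5, 0.25), origin = 1)
#' step_value(km, c(0, 1, 1.5, 10))
#' @export
step_curve <- function(time, estimate, origin) {
  if (length(time) != length(estimate)) {
    abort("`time` and `estimate` must have the same length.")
  }
  if (length(time) && (any(!is.finite(time)) || any(time < 0))) {
    abort("Jump times must be finite and non-negative.")
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    abort("Jump times must be strictly increasing.")
  }
  out <- tibble(time = as.double(time), estimate = as.double(estimate))
  attr(out, "origin") <- as.double(origin)
  class(out) <- c("step_curve", class(out))
  out
}

#' Evaluate a step curve
#'
#' Right-continuous evaluation: the value at `t` is the value attached to the
#' largest jump time less than or equal to `t`, or the origin value if no
#' jump has occurred yet.
#'
#' @param curve A [step_curve()].
#' @param t Times at which to evaluate.
#' @return Numeric vector, one value per element of `t`.
#' @export
step_value <- function(curve, t) {
  stopifnot(inherits(curve, "step_curve"))
  y0 <- attr(curve, "origin")
  c(y0, curve$estimate)[findInterval(t, curve$time) + 1L]
}

#' @export
print.step_curve <- function(x, ...) {
  cat("<step_curve> origin =", format(attr(x, "origin")),
      "with", nrow(x), "jump(s)\n")
  NextMethod()
}

# evaluate jump representation (ut sorted, cumulative values) on a grid
step_eval_raw <- function(ut, values, grid, origin = 0) {
  c(origin, values)[findInterval(grid, ut) + 1L]
}
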