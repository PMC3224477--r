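#' Risk table for competing-risks data
#'
#' Tabulates, at each distinct observed event time, the number of subjects
#' at risk, the number failing from the cause of interest (cause code 1),
#' and the number failing from any cause. Cause codes follow the competing
#' risks convention: `0` censored, `1` event of interest, `2` competing
#' event. Censored observations tied with an event time remain in the risk
#' set at that time.
#'
#' @param time Non-negative observation times.
#' @param cause Integer cause codes in `{0, 1, 2}`.
#' @return A tibble with columns `time`, `n_risk`, `n_interest`
#'   (cause 1 count), `n_event` (cause 1 or 2 count), one row per distinct
#'   event time in ascending order.
#' @export
risk_table <- function(time, cause) {
  check_time_cause(time, cause)
  rc <- risk_counts(time, as.integer(cause))
  tibble(time = rc$ut, n_risk = rc$n_risk,
         n_interest = rc$c1, n_event = rc$d)
}

check_time_cause <- function(time, cause) {
  if (length(time) != length(cause)) {
    abort("`time` and `cause` must have the same length.")
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    abort("Observation times must be finite and non-negative.")
  }
  if (!all(cause %in% c(0L, 1L, 2L))) {
    abort("Cause codes must be 0 (censored), 1 (event of interest) or 2 (competing).")
  }
  invisible(TRUE)
}

#' Kaplan-Meier product-limit survival curve
#'
#' All-cause or cause-subset survival: at each distinct event time the curve
#' drops by the factor `1 - d/n`, where `d` counts failures from the causes
#' in `interest` and `n` is the at-risk count. Observations failing from
#' causes outside `interest` are treated as censored at their time.
#'
#' @inheritParams risk_table
#' @param interest Non-empty set of cause codes counted as events
#'   (default `c(1, 2)`, i.e. all-cause survival).
#' @return A [step_curve()] starting at 1, non-increasing.
#' @export
kaplan_meier <- function(time, cause, interest = c(1, 2)) {
  check_time_cause(time, cause)
  if (!length(interest)) abort("`interest` must name at least one cause.")
  status <- as.integer(cause %in% interest)
  rc <- risk_counts(time, status)
  S <- cumprod(1 - rc$c1 / rc$n_risk)
  step_curve(rc$ut, S, origin = 1)
}

#' Nelson-Aalen cause-specific hazard increments
#'
#' The discrete hazard increment for the cause of interest at each event
#' time, `n_interest / n_risk`.
#'
#' @param table A [risk_table()].
#' @return The table with an added `increment` column.
#' @export
na_increments <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("time", "n_risk", "n_interest") %in% names(table)))
  mutate(as_tibble(table), increment = .data$n_interest / .data$n_risk)
}

#' Cumulative incidence function under competing risks
#'
#' Aalen-Johansen-type estimator: the jump at each event time is the
#' Nelson-Aalen cause-specific hazard increment for the cause of interest
#' multiplied by the all-cause Kaplan-Meier survival evaluated just before
#' that time. With a single cause and no competing events this reduces
#' exactly to one minus the Kaplan-Meier curve.
#'
#' @inheritParams risk_table
#' @param interest The cause of interest, `1` or `2`.
#' @return A [step_curve()] starting at 0, non-decreasing.
#' @export
cumulative_incidence <- function(time, cause, interest = 1) {
  check_time_cause(time, cause)
  if (!interest %in% c(1, 2)) abort("`interest` must be cause 1 or 2.")
  cause <- as.integer(cause)
  if (interest == 2) cause <- c(0L, 2L, 1L)[cause + 1L]
  rc <- risk_counts(time, cause)
  if (!length(rc$ut)) return(step_curve(numeric(0), numeric(0), origin = 0))
  S <- cumprod(1 - rc$d / rc$n_risk)
  S_lag <- c(1, S[-length(S)])
  I <- cumsum(rc$c1 / rc$n_risk * S_lag)
  step_curve(rc$ut, I, origin = 0)
}
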