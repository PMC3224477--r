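#' Tidy a current-survival curve
#'
#' @param x A `current_curve` as returned by [cci()], [clfs()] or
#'   [cci_markov()].
#' @param ... Unused.
#' @return A plain tibble with the curve columns (`time`, `estimate` and,
#'   if present, `lower`, `upper`).
#' @method tidy current_curve
#' @export
tidy.current_curve <- function(x, ...) {
  as_tibble(x[, intersect(c("time", "estimate", "lower", "upper"), names(x))])
}

#' One-row summary of a current-survival curve
#'
#' @inheritParams tidy.current_curve
#' @return A tibble with columns `measure`, `n`, `r`, `B`, `level`,
#'   `n_times`, `final_time`, `final_estimate`.
#' @method glance current_curve
#' @export
glance.current_curve <- function(x, ...) {
  tibble(measure = attr(x, "measure"),
         n = attr(x, "n"),
         r = attr(x, "r"),
         B = attr(x, "B"),
         level = attr(x, "level"),
         n_times = nrow(x),
         final_time = if (nrow(x)) max(x$time) else NA_real_,
         final_estimate = if (nrow(x)) x$estimate[which.max(x$time)] else NA_real_)
}

#' @export
print.current_curve <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<current_curve> measure = %s, n = %d, r = %d%s\n",
              g$measure, g$n, g$r,
              if (g$B > 0) sprintf(", %d%% bands (B = %d)",
                                   round(100 * g$level), g$B) else ""))
  NextMethod()
}

#' Summarise a curve at reporting times
#'
#' Evaluates a curve tibble right-continuously at a set of clinically
#' meaningful reporting times (by default the response-assessment schedule
#' 3, 6, 12, 18, 24, 36 and 48 months).
#'
#' @param curve A `current_curve` or any tibble with `time` and `estimate`
#'   (and optionally `lower`/`upper`) columns.
#' @param times Reporting times.
#' @param origin Curve value before the first jump (1 for survival-type,
#'   0 for incidence-type curves); inferred from the measure when possible.
#' @return A tibble with one row per reporting time.
#' @export
report_at <- function(curve, times = c(3, 6, 12, 18, 24, 36, 48),
                      origin = NULL) {
  stopifnot(all(c("time", "estimate") %in% names(curve)))
  origin <- origin %||%
    if (identical(attr(curve, "measure"), "clfs")) 1 else 0
  pick <- function(col, y0) c(y0, curve[[col]])[findInterval(times, curve$time) + 1L]
  out <- tibble(time = as.double(times), estimate = pick("estimate", origin))
  if (all(c("lower", "upper") %in% names(curve))) {
    out$lower <- pick("lower", origin)
    out$upper <- pick("upper", origin)
  }
  out
}

#' Plot a current-survival curve
#'
#' Step plot of the estimate with an optional percentile-band ribbon.
#'
#' @param object A `current_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot current_curve
#' @export
autoplot.current_curve <- function(object, ...) {
  measure <- attr(object, "measure") %||% "estimate"
  lab <- c(cci = "Current cumulative incidence",
           clfs = "Current leukaemia-free survival",
           cci_markov = "Current cumulative incidence (Markov multi-state)")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$estimate))
  if (all(c("lower", "upper") %in% names(object))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.2, stat = "identity")
  }
  p + ggplot2::geom_step() +
    ggplot2::labs(x = "Time", y = lab[measure] %||% measure)
}

#' Plot the component curves of an estimator
#'
#' @param components Output of [cci_components()] or [clfs_components()].
#' @return A ggplot object, one panel per remission depth.
#' @export
plot_components <- function(components) {
  stopifnot(all(c("i", "component", "time", "estimate") %in% names(components)))
  ggplot2::ggplot(components,
                  ggplot2::aes(x = .data$time, y = .data$estimate,
                               colour = .data$component)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~i, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time", y = "Probability")
}
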