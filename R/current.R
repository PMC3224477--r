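#' Current cumulative incidence and current leukaemia-free survival
#'
#' `cci()` estimates the probability that a patient is alive and in (any)
#' disease remission at time `t` after therapy initiation. It is a linear
#' combination of cause-specific cumulative incidence curves: for each
#' remission depth `i`, the incidence of achieving the i-th remission minus
#' the incidence of losing it minus the incidence of dying while in it,
#' summed over depths.
#'
#' `clfs()` estimates the probability that a patient who achieved a first
#' remission is alive and in (any) remission at time `t` after that first
#' achievement. It is a linear combination of Kaplan-Meier curves computed
#' on the first-remission clock: the survival of the first remission plus,
#' for each deeper depth, the difference between the survival against the
#' i-th loss and the survival against the i-th achievement.
#'
#' Both estimators are unconstrained linear combinations of separately
#' estimated curves, so under heavy censoring they can transiently leave
#' the unit interval and need not be monotone; values are reported raw
#' (with a warning when they exit `[0, 1]`) rather than clipped.
#'
#' @param histories An `event_history` tibble (see [as_event_history()]) on
#'   the therapy-initiation clock.
#' @param grid Evaluation times. Defaults to 0 plus every observed
#'   component event time (lossless step representation).
#' @param B Number of bootstrap resamples for percentile confidence bands;
#'   `0` (default) for point estimates only.
#' @param level Confidence level for the bands.
#' @param seed Integer seed controlling the bootstrap resampling.
#' @param r Remission depth override; defaults to the depth observed in the
#'   cohort.
#'
#' @return A tibble of class `current_curve` with columns `time`,
#'   `estimate` and, when `B > 0`, `lower` and `upper`; metadata (measure,
#'   n, r, B, level, seed) is carried in attributes and surfaced by
#'   [glance()].
#' @seealso [cci_components()], [clfs_components()], [cci_markov()]
#' @export
cci <- function(histories, grid = NULL, B = 0, level = 0.95, seed = NULL,
                r = NULL) {
  histories <- assert_history(histories, clock = "origin")
  v <- cohort_vectors(histories, r = r)
  grid <- sort(unique(as.double(grid %||% vectors_grid(v))))
  est <- cci_kernel(v, grid)
  out <- tibble(time = grid, estimate = est)
  if (B > 0) {
    bands <- boot_bands(v, kernel = cci_kernel, grid = grid, B = B,
                        level = level, seed = seed)
    out$lower <- bands$lower
    out$upper <- bands$upper
  }
  warn_unit_interval(est, "CCI")
  new_current_curve(out, measure = "cci", n = v$n, r = v$r, B = B,
                    level = level, seed = seed)
}

#' @rdname cci
#' @export
clfs <- function(histories, grid = NULL, B = 0, level = 0.95, seed = NULL,
                 r = NULL) {
  histories <- assert_history(histories, clock = "origin")
  v <- cohort_vectors(histories, r = r)
  if (v$r == 0 || !any(v$ac[, 1] == 1L)) {
    abort("No patient achieved a remission; CLFS is undefined.")
  }
  grid <- sort(unique(as.double(grid %||% clfs_grid(v))))
  est <- clfs_kernel(v, grid)
  out <- tibble(time = grid, estimate = est)
  if (B > 0) {
    bands <- boot_bands(v, kernel = clfs_kernel, grid = grid, B = B,
                        level = level, seed = seed)
    out$lower <- bands$lower
    out$upper <- bands$upper
  }
  warn_unit_interval(est, "CLFS")
  new_current_curve(out, measure = "clfs", n = v$n, r = v$r, B = B,
                    level = level, seed = seed)
}

warn_unit_interval <- function(est, label) {
  eps <- 1e-10
  if (any(est < -eps) || any(est > 1 + eps)) {
    warn(sprintf(
      "%s estimate leaves [0, 1] (range %.4f to %.4f); values are reported raw, not clipped.",
      label, min(est), max(est)))
  }
  invisible(NULL)
}

new_current_curve <- function(df, measure, n, r, B = 0, level = NA_real_,
                              seed = NULL) {
  attr(df, "measure") <- measure
  attr(df, "n") <- as.integer(n)
  attr(df, "r") <- as.integer(r)
  attr(df, "B") <- as.integer(B)
  attr(df, "level") <- if (B > 0) level else NA_real_
  attr(df, "seed") <- seed
  class(df) <- c("current_curve", class(df))
  df
}

#' Component curves of the current cumulative incidence
#'
#' For each remission depth `i`, the three cumulative incidence components
#' that enter the current cumulative incidence: `achievement` (the i-th
#' remission is reached), `loss` (the i-th remission is lost) and
#' `death_in_remission` (death while in the i-th remission). The loss and
#' death-in-remission components share the same all-cause survival factor,
#' estimated from the loss transition vectors.
#'
#' @inheritParams cci
#' @return A tibble with columns `i`, `component`, `time`, `estimate`;
#'   each (`i`, `component`) group is a right-continuous step curve
#'   starting at 0 (rows only at its jump times).
#' @export
cci_components <- function(histories, r = NULL) {
  histories <- assert_history(histories, clock = "origin")
  v <- cohort_vectors(histories, r = r)
  if (v$r == 0) {
    return(tibble(i = integer(0), component = character(0),
                  time = double(0), estimate = double(0)))
  }
  rows <- vector("list", 3L * v$r)
  k <- 0L
  for (i in seq_len(v$r)) {
    ca <- cumulative_incidence(v$at[, i], v$ac[, i], interest = 1)
    grid_l <- sort(unique(v$lt[v$lc[, i] != 0L, i]))
    cl <- cif_on_grid(v$lt[, i], v$lc[, i], grid_l, marker = v$lrem[, i])
    rows[[k <- k + 1L]] <- tibble(i = i, component = "achievement",
                                  time = ca$time, estimate = ca$estimate)
    rows[[k <- k + 1L]] <- tibble(i = i, component = "loss",
                                  time = grid_l, estimate = cl$I1)
    rows[[k <- k + 1L]] <- tibble(i = i, component = "death_in_remission",
                                  time = grid_l, estimate = cl$I2m)
  }
  bind_rows(rows)
}

#' Component curves of the current leukaemia-free survival
#'
#' Kaplan-Meier survival curves on the first-remission clock, restricted to
#' patients who achieved a first remission: for `i = 1` the survival
#' against first loss or death in first remission (the common
#' leukaemia-free survival); for `i >= 2` the survival against the i-th
#' loss or prior death (`component = "loss"`) and against the i-th
#' achievement or prior death (`component = "achievement"`).
#'
#' @inheritParams cci
#' @return A tibble with columns `i`, `component`, `time`, `estimate`;
#'   step curves starting at 1.
#' @export
clfs_components <- function(histories, r = NULL) {
  histories <- assert_history(histories, clock = "origin")
  v <- cohort_vectors(histories, r = r)
  sel <- if (v$r > 0) which(v$ac[, 1] == 1L) else integer(0)
  if (!length(sel)) abort("No patient achieved a remission; CLFS is undefined.")
  t1 <- v$at[sel, 1]
  rows <- list()
  km1 <- kaplan_meier(v$lt[sel, 1] - t1, as.integer(v$lc[sel, 1] != 0L),
                      interest = 1)
  rows[[1]] <- tibble(i = 1L, component = "loss",
                      time = km1$time, estimate = km1$estimate)
  if (v$r >= 2) {
    for (i in 2:v$r) {
      km_a <- kaplan_meier(v$at[sel, i] - t1, as.integer(v$ac[sel, i] != 0L),
                           interest = 1)
      km_l <- kaplan_meier(v$lt[sel, i] - t1, as.integer(v$lc[sel, i] != 0L),
                           interest = 1)
      rows[[length(rows) + 1]] <- tibble(i = i, component = "achievement",
                                         time = km_a$time, estimate = km_a$estimate)
      rows[[length(rows) + 1]] <- tibble(i = i, component = "loss",
                                         time = km_l$time, estimate = km_l$estimate)
    }
  }
  bind_rows(rows)
}

#' Common leukaemia-free survival
#'
#' The conventional single-event measure: Kaplan-Meier survival against the
#' first remission loss or death in first remission, on the
#' first-remission clock. Equals [clfs()] when the cohort's remission
#' depth is 1.
#'
#' @inheritParams cci
#' @return A tibble of class `current_curve` (`measure = "lfs"`).
#' @export
common_lfs <- function(histories, grid = NULL, B = 0, level = 0.95,
                       seed = NULL) {
  clfs(histories, grid = grid, B = B, level = level, seed = seed, r = 1)
}

#' Directly counted state-occupation fraction
#'
#' Brute-force counting estimate of the probability of being alive and in
#' remission: at each time, the fraction of patients whose history places
#' them in a remission state with death not yet occurred. On the
#' therapy-initiation clock every patient contributes to the denominator;
#' on the first-remission clock patients start in remission. Counting is
#' exact for fully observed (uncensored) cohorts, where it coincides with
#' [cci()] / [clfs()]; under censoring it is biased and useful only as a
#' diagnostic.
#'
#' @param histories An `event_history` tibble (either clock).
#' @param times Evaluation times.
#' @return A tibble with columns `time` and `estimate`.
#' @export
occupied_fraction <- function(histories, times) {
  histories <- assert_history(histories)
  hs <- history_summary(histories)
  start_in_rem <- hs$starts_in_remission[1]
  n <- nrow(hs)
  est <- vapply(times, function(t) {
    n_ach <- vapply(hs$achieve_times, function(a) sum(a <= t), 0L)
    n_los <- vapply(hs$lose_times, function(l) sum(l <= t), 0L)
    dead <- hs$terminal_kind == "death" & hs$terminal_time <= t
    depth <- n_ach - n_los + as.integer(start_in_rem)
    sum(depth == 1L & !dead) / n
  }, 0)
  tibble(time = as.double(times), estimate = est)
}

#' Number of patients under observation
#'
#' @param histories An `event_history` tibble.
#' @param times Evaluation times.
#' @return A tibble with columns `time` and `n_risk` (patients whose
#'   terminal event has not occurred before `time`).
#' @export
at_risk <- function(histories, times) {
  histories <- assert_history(histories)
  hs <- history_summary(histories)
  tibble(time = as.double(times),
         n_risk = vapply(times, function(t) sum(hs$terminal_time >= t), 0L))
}
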