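#' Resample patients with replacement
#'
#' Efron bootstrap procedure II at the patient level: whole histories are
#' drawn with replacement, preserving within-patient dependence across
#' remission cycles. The resampled cohort has the same size as the
#' original; resampled copies of a patient get a replicate suffix so the
#' result is again a valid `event_history`.
#'
#' @param histories An `event_history` tibble.
#' @param seed Optional integer seed for reproducibility.
#' @return An `event_history` tibble of the same cohort size.
#' @export
resample_patients <- function(histories, seed = NULL) {
  histories <- assert_history(histories)
  if (!is.null(seed)) set.seed(seed)
  idx <- split(seq_len(nrow(histories)), histories$patient_id)
  n <- length(idx)
  if (n == 0) abort("Empty cohort.")
  draw <- sample.int(n, n, replace = TRUE)
  parts <- lapply(seq_along(draw), function(k) {
    rows <- idx[[draw[k]]]
    out <- histories[rows, ]
    out$patient_id <- sprintf("%s.b%03d", out$patient_id[1], k)
    out
  })
  as_event_history(bind_rows(parts), clock = attr(histories, "clock"))
}

#' Efron bootstrap procedure I for a single endpoint
#'
#' Separate resampling with replacement from the Kaplan-Meier estimates of
#' the event-time distribution and of the censoring-time distribution
#' (reverse Kaplan-Meier); each bootstrap observation is the pairwise
#' minimum of an event draw and a censoring draw with the corresponding
#' indicator. When either Kaplan-Meier curve does not reach zero, the
#' missing mass lies beyond follow-up: such draws cannot win the minimum
#' and a message is emitted; if both draws fall beyond follow-up the
#' observation is recorded as censored at the largest observed time.
#'
#' @param time Non-negative observation times.
#' @param status Event indicator (1 event, 0 censored).
#' @param seed Optional integer seed.
#' @return A tibble with columns `time`, `status` of the same length.
#' @export
resample_efron1 <- function(time, status, seed = NULL) {
  if (length(time) != length(status)) {
    abort("`time` and `status` must have the same length.")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(time)
  # draws from the Kaplan-Meier mass function; mass not reached by the KM
  # curve ("cure" fraction beyond follow-up) is drawn as +Inf so that such
  # draws can never win the minimum, i.e. they yield censored observations
  # at the other coordinate
  draw_from <- function(tm, st, what) {
    rc <- risk_counts(tm, as.integer(st))
    if (!length(rc$ut)) {
      inform(sprintf(
        "No observed %s times; the whole %s-time distribution lies beyond follow-up.",
        what, what))
      return(rep(Inf, n))
    }
    S <- cumprod(1 - rc$c1 / rc$n_risk)
    mass <- c(1, S[-length(S)]) - S
    rest <- S[length(S)]
    atoms <- rc$ut
    if (rest > 1e-12) {
      inform(sprintf(
        "Estimated %s-time distribution is defective (mass %.3f beyond the largest observed time).",
        what, rest))
      atoms <- c(atoms, Inf)
      mass <- c(mass, rest)
    }
    atoms[sample.int(length(atoms), n, replace = TRUE, prob = mass)]
  }
  x <- draw_from(time, status, "event")
  cn <- draw_from(time, 1 - status, "censoring")
  obs <- pmin(x, cn)
  st_new <- as.integer(is.finite(x) & x <= cn)
  # both draws beyond follow-up: censored at the end of observation
  beyond <- !is.finite(obs)
  obs[beyond] <- max(time)
  tibble(time = obs, status = st_new)
}

# nearest-rank (type 1) percentile over replicate curves stored as a
# B x length(grid) matrix; rows that are entirely NA are failed replicates
percentile_from_matrix <- function(reps, level) {
  ok <- !apply(is.na(reps), 1, all)
  n_fail <- sum(!ok)
  if (n_fail > 0.01 * nrow(reps)) {
    abort(sprintf(
      "%d of %d bootstrap replicates failed (> 1%%); the cohort is too fragile for percentile bands.",
      n_fail, nrow(reps)))
  }
  reps <- reps[ok, , drop = FALSE]
  m <- nrow(reps)
  alpha <- 1 - level
  lo_i <- max(1L, ceiling(m * alpha / 2))
  hi_i <- max(1L, ceiling(m * (1 - alpha / 2)))
  lower <- numeric(ncol(reps))
  upper <- numeric(ncol(reps))
  for (j in seq_len(ncol(reps))) {
    x <- sort(reps[, j])
    lower[j] <- x[lo_i]
    upper[j] <- x[hi_i]
  }
  list(lower = lower, upper = upper, n_failed = n_fail)
}

# fast path: resample patient indices and re-run a vector kernel
boot_bands <- function(v, kernel, grid, B, level, seed) {
  boot_bands_index(
    n = v$n,
    stat = function(idx) kernel(v, grid, idx = idx),
    grid = grid, B = B, level = level, seed = seed
  )
}

boot_bands_index <- function(n, stat, grid, B, level, seed) {
  if (B < 2) abort("`B` must be at least 2.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  if (!is.null(seed)) set.seed(seed)
  reps <- matrix(NA_real_, B, length(grid))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(stat(idx), error = function(e) NULL)
    if (!is.null(val)) reps[b, ] <- val
  }
  percentile_from_matrix(reps, level)
}

#' Percentile bootstrap bands for an arbitrary curve statistic
#'
#' Patient-level (Efron procedure II) bootstrap: `B` cohorts are drawn with
#' replacement, the statistic is evaluated on each, and point-wise
#' nearest-rank percentile limits are returned. Replicates on which the
#' statistic fails (for example a resample without any remission when the
#' statistic is CLFS) are recorded as missing; more than 1% failed
#' replicates aborts with a diagnostic. For the built-in estimators prefer
#' the `B` argument of [cci()], [clfs()] and [cci_markov()], which uses a
#' faster resampling path with identical semantics.
#'
#' @param histories An `event_history` tibble.
#' @param statistic Function `(histories, grid) -> numeric` returning the
#'   curve values on `grid`.
#' @param grid Evaluation times.
#' @param B Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @return A tibble with columns `time`, `estimate`, `lower`, `upper`.
#' @export
percentile_band <- function(histories, statistic, grid, B = 500,
                            level = 0.95, seed = NULL) {
  histories <- assert_history(histories)
  if (B < 2) abort("`B` must be at least 2.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  idx <- split(seq_len(nrow(histories)), histories$patient_id)
  n <- length(idx)
  clock <- attr(histories, "clock")
  point <- statistic(histories, grid)
  stat_idx <- function(pick) {
    parts <- lapply(seq_along(pick), function(k) {
      out <- histories[idx[[pick[k]]], ]
      out$patient_id <- sprintf("b%04d", k)
      out
    })
    boot <- bind_rows(parts)
    attr(boot, "clock") <- clock
    class(boot) <- c("event_history", class(boot))
    statistic(boot, grid)
  }
  bands <- boot_bands_index(n = n, stat = stat_idx, grid = grid, B = B,
                            level = level, seed = seed)
  tibble(time = as.double(grid), estimate = point,
         lower = bands$lower, upper = bands$upper)
}
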