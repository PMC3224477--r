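# Internal vectorised kernels.
#
# All estimators reduce to two scalar recursions over the ranked distinct
# event times of a (time, cause) sample:
#   * product-limit survival  S(t_j) = prod_{k<=j} (1 - d_k / n_k)
#   * cumulative incidence    I(t_j) = sum_{k<=j} (c_k / n_k) * S(t_{k-1})
# where n_k is the at-risk count, d_k the all-cause event count and c_k the
# count for the cause of interest. Censored observations tied with an event
# time stay in the risk set at that time.

# counts at distinct event times; time must be a numeric vector, cause an
# integer vector over {0 = censored, 1, 2}
risk_counts <- function(time, cause, marker = NULL) {
  o <- order(time)
  t <- time[o]
  cz <- cause[o]
  n <- length(t)
  ev <- cz != 0L
  if (!any(ev)) {
    return(list(ut = numeric(0), n_risk = integer(0), c1 = integer(0),
                c2 = integer(0), c2m = integer(0), d = integer(0)))
  }
  te <- t[ev]
  ut <- te[!duplicated(te)]
  n_risk <- n - findInterval(ut, t, left.open = TRUE)
  j <- match(te, ut)
  cze <- cz[ev]
  c1 <- tabulate(j[cze == 1L], length(ut))
  c2 <- tabulate(j[cze == 2L], length(ut))
  c2m <- if (is.null(marker)) integer(length(ut)) else {
    mk <- marker[o][ev]
    tabulate(j[cze == 2L & mk], length(ut))
  }
  list(ut = ut, n_risk = n_risk, c1 = c1, c2 = c2, c2m = c2m, d = c1 + c2)
}

# Kaplan-Meier on a 0/1 status vector, evaluated on `grid`
km_on_grid <- function(time, status, grid) {
  rc <- risk_counts(time, as.integer(status != 0))
  if (!length(rc$ut)) return(rep(1, length(grid)))
  S <- cumprod(1 - rc$c1 / rc$n_risk)
  step_eval_raw(rc$ut, S, grid, origin = 1)
}

# cause-1 (and optionally marked cause-2) cumulative incidence on `grid`,
# with the all-cause Kaplan-Meier as the shared survival factor
cif_on_grid <- function(time, cause, grid, marker = NULL) {
  rc <- risk_counts(time, cause, marker)
  if (!length(rc$ut)) {
    zero <- rep(0, length(grid))
    return(list(I1 = zero, I2m = zero))
  }
  S <- cumprod(1 - rc$d / rc$n_risk)
  S_lag <- c(1, S[-length(S)])
  I1 <- cumsum(rc$c1 / rc$n_risk * S_lag)
  out <- list(I1 = step_eval_raw(rc$ut, I1, grid, origin = 0))
  I2m <- cumsum(rc$c2m / rc$n_risk * S_lag)
  out$I2m <- step_eval_raw(rc$ut, I2m, grid, origin = 0)
  out
}

# Per-patient transition vectors in matrix form. Rows are patients; column
# i holds the time to / cause of the i-th achievement (at, ac) and the i-th
# loss (lt, lc); lrem marks deaths occurring while in the i-th remission.
cohort_vectors <- function(histories, r = NULL) {
  hs <- history_summary(histories)
  n <- nrow(hs)
  m_ach <- lengths(hs$achieve_times)
  r_data <- max(m_ach, 0L)
  r <- as.integer(r %||% r_data)
  if (is.na(r) || r < 0) abort("`r` must be a non-negative integer.")
  at <- matrix(0, n, r); ac <- matrix(0L, n, r)
  lt <- matrix(0, n, r); lc <- matrix(0L, n, r)
  lrem <- matrix(FALSE, n, r)
  if (r > 0) {
    dead <- hs$terminal_kind == "death"
    tt <- hs$terminal_time
    m_los <- lengths(hs$lose_times)
    for (i in seq_len(r)) {
      has_a <- m_ach >= i
      ai <- rep(NA_real_, n)
      ai[has_a] <- vapply(which(has_a), function(k) hs$achieve_times[[k]][i], 0)
      at[, i] <- ifelse(has_a, ai, tt)
      ac[, i] <- ifelse(has_a, 1L, ifelse(dead, 2L, 0L))
      has_l <- m_los >= i
      li <- rep(NA_real_, n)
      li[has_l] <- vapply(which(has_l), function(k) hs$lose_times[[k]][i], 0)
      lt[, i] <- ifelse(has_l, li, tt)
      lc[, i] <- ifelse(has_l, 1L, ifelse(dead, 2L, 0L))
      lrem[, i] <- !has_l & dead & has_a
    }
  }
  list(patients = hs$patient_id, at = at, ac = ac, lt = lt, lc = lc,
       lrem = lrem, r = r, n = n)
}

# default evaluation grid: 0 plus every observed event time of any component
vectors_grid <- function(v) {
  tms <- c(v$at[v$ac != 0L], v$lt[v$lc != 0L])
  sort(unique(c(0, tms)))
}

# CCI on a grid from precomputed vectors; idx selects a patient (bootstrap)
# subset. Returns the numeric curve.
cci_kernel <- function(v, grid, idx = NULL) {
  if (v$r == 0) return(rep(0, length(grid)))
  total <- rep(0, length(grid))
  for (i in seq_len(v$r)) {
    if (is.null(idx)) {
      a_t <- v$at[, i]; a_c <- v$ac[, i]
      l_t <- v$lt[, i]; l_c <- v$lc[, i]; l_m <- v$lrem[, i]
    } else {
      a_t <- v$at[idx, i]; a_c <- v$ac[idx, i]
      l_t <- v$lt[idx, i]; l_c <- v$lc[idx, i]; l_m <- v$lrem[idx, i]
    }
    Ia <- cif_on_grid(a_t, a_c, grid)$I1
    Il <- cif_on_grid(l_t, l_c, grid, marker = l_m)
    total <- total + Ia - Il$I1 - Il$I2m
  }
  total
}

# CLFS on a grid (grid on the first-remission clock) from origin-clock
# vectors. Returns NULL when the (re)sample contains no first remission.
clfs_kernel <- function(v, grid, idx = NULL) {
  sel <- if (is.null(idx)) seq_len(v$n) else idx
  if (v$r == 0) return(NULL)
  sel <- sel[v$ac[sel, 1] == 1L]
  if (!length(sel)) return(NULL)
  t1 <- v$at[sel, 1]
  total <- km_on_grid(v$lt[sel, 1] - t1, v$lc[sel, 1] != 0L, grid)
  if (v$r >= 2) {
    for (i in 2:v$r) {
      Si <- km_on_grid(v$at[sel, i] - t1, v$ac[sel, i] != 0L, grid)
      Si_star <- km_on_grid(v$lt[sel, i] - t1, v$lc[sel, i] != 0L, grid)
      total <- total + Si_star - Si
    }
  }
  total
}

# default CLFS grid: 0 plus reset-clock event times
clfs_grid <- function(v) {
  sel <- which(v$ac[, 1] == 1L)
  if (!length(sel)) return(0)
  t1 <- v$at[sel, 1]
  tms <- numeric(0)
  for (i in seq_len(v$r)) {
    tms <- c(tms,
             (v$lt[sel, i] - t1)[v$lc[sel, i] != 0L],
             if (i >= 2) (v$at[sel, i] - t1)[v$ac[sel, i] != 0L])
  }
  sort(unique(c(0, tms)))
}
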