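#' Progressive multi-state state space
#'
#' Unrolls the remission-relapse cycle into a progressive (acyclic)
#' multi-state model: a diagnosis state, one remission and one relapse
#' state per depth `1..r`, and death. By default death is a single
#' absorbing state (`2r + 2` states), which yields occupation
#' probabilities for the remission states identical to the bookkeeping
#' with stage-specific death states. With `split_death = TRUE` each
#' pre-death state gets its own death state (diagnosis, each remission,
#' each relapse except the deepest), giving `4r + 1` states -- nine for
#' `r = 2`.
#'
#' @param r Maximum remission depth, a positive integer.
#' @param split_death Split death into stage-specific absorbing states.
#' @return A list of class `progressive_states` with elements `states`
#'   (tibble: `index`, `label`, `type`, `depth`) and `transitions`
#'   (tibble: `from`, `to` state indices).
#' @export
progressive_states <- function(r, split_death = FALSE) {
  r <- as.integer(r)
  if (is.na(r) || r < 1) abort("`r` must be a positive integer.")
  states <- tibble(index = 1L, label = "diagnosis", type = "diagnosis",
                   depth = 0L)
  add <- function(states, label, type, depth) {
    bind_rows(states, tibble(index = nrow(states) + 1L, label = label,
                             type = type, depth = as.integer(depth)))
  }
  if (split_death) {
    states <- add(states, "death-from-diagnosis", "death", 0L)
    for (i in seq_len(r)) {
      states <- add(states, sprintf("remission-%d", i), "remission", i)
      states <- add(states, sprintf("death-from-remission-%d", i), "death", i)
      states <- add(states, sprintf("relapse-%d", i), "relapse", i)
      if (i < r) {
        states <- add(states, sprintf("death-from-relapse-%d", i), "death", i)
      }
    }
  } else {
    for (i in seq_len(r)) {
      states <- add(states, sprintf("remission-%d", i), "remission", i)
      states <- add(states, sprintf("relapse-%d", i), "relapse", i)
    }
    states <- add(states, "death", "death", NA)
  }
  idx <- function(label) states$index[states$label == label]
  death_for <- function(label) {
    if (!split_death) return(idx("death"))
    d <- idx(paste0("death-from-", label))
    if (length(d)) d else integer(0)
  }
  trans <- list(tibble(from = idx("diagnosis"),
                       to = c(death_for("diagnosis"), idx("remission-1"))))
  for (i in seq_len(r)) {
    rem <- sprintf("remission-%d", i)
    rel <- sprintf("relapse-%d", i)
    trans[[length(trans) + 1]] <- tibble(from = idx(rem),
                                         to = c(death_for(rem), idx(rel)))
    nxt <- if (i < r) idx(sprintf("remission-%d", i + 1)) else integer(0)
    trans[[length(trans) + 1]] <- tibble(from = idx(rel),
                                         to = c(death_for(rel), nxt))
  }
  out <- list(states = states, transitions = bind_rows(trans), r = r,
              split_death = split_death)
  class(out) <- "progressive_states"
  out
}

#' @export
print.progressive_states <- function(x, ...) {
  cat(sprintf("<progressive_states> r = %d, %d states (%s death)\n",
              x$r, nrow(x$states),
              if (x$split_death) "stage-specific" else "single absorbing"))
  print(x$states, ...)
  invisible(x)
}

# per-patient sojourn records (from, to, tstart, tstop), to = NA when the
# spell ends by censoring; state indices follow `space`
history_records <- function(histories, space) {
  hs <- history_summary(histories)
  labels <- space$states$label
  idx_of <- setNames(space$states$index, labels)
  allowed <- paste(space$transitions$from, space$transitions$to)
  recs <- vector("list", nrow(hs))
  for (k in seq_len(nrow(hs))) {
    a <- hs$achieve_times[[k]]
    l <- hs$lose_times[[k]]
    tt <- hs$terminal_time[k]
    dead <- hs$terminal_kind[k] == "death"
    m <- length(a)
    states_seq <- "diagnosis"
    times_seq <- 0
    for (i in seq_len(m)) {
      states_seq <- c(states_seq, sprintf("remission-%d", i))
      times_seq <- c(times_seq, a[i])
      if (length(l) >= i) {
        states_seq <- c(states_seq, sprintf("relapse-%d", i))
        times_seq <- c(times_seq, l[i])
      }
    }
    n_sp <- length(states_seq)
    from <- states_seq
    to <- c(states_seq[-1], NA)
    tstart <- times_seq
    tstop <- c(times_seq[-1], tt)
    if (dead) {
      last <- states_seq[n_sp]
      dlab <- if (space$split_death) paste0("death-from-", last) else "death"
      if (!dlab %in% labels) {
        abort(sprintf(
          "Observed transition %s -> death has no state in the space (split_death with deepest relapse).",
          last))
      }
      to[n_sp] <- dlab
    }
    if (any(!states_seq %in% labels)) {
      abort(sprintf("Patient %s reaches depth beyond the state space (r = %d).",
                    hs$patient_id[k], space$r))
    }
    recs[[k]] <- tibble(patient_id = hs$patient_id[k],
                        from = unname(idx_of[from]),
                        to = unname(idx_of[to]),
                        tstart = tstart, tstop = tstop)
  }
  out <- bind_rows(recs)
  obs <- !is.na(out$to)
  if (any(obs) &&
      !all(paste(out$from[obs], out$to[obs]) %in% allowed)) {
    abort("Observed a transition that is not allowed by the progressive state space.")
  }
  out
}

# Aalen-Johansen product-integral over transition records.
# Returns list(ut, P) with P[k, ] the first row of the accumulated matrix
# just after ut[k], plus the full final matrix for diagnostics.
aj_product <- function(records, K) {
  obs <- records[!is.na(records$to), , drop = FALSE]
  ut <- sort(unique(obs$tstop))
  P <- diag(K)
  row0 <- matrix(0, length(ut), K)
  # at-risk per state: sorted entry/exit times
  starts <- split(records$tstart, records$from)
  stops <- split(records$tstop, records$from)
  starts <- lapply(starts, sort)
  stops <- lapply(stops, sort)
  agg <- obs |>
    group_by(.data$tstop, .data$from, .data$to) |>
    summarise(count = dplyr::n(), .groups = "drop") |>
    arrange(.data$tstop)
  split_by_time <- split(agg, factor(agg$tstop, levels = ut))
  for (k in seq_along(ut)) {
    g <- split_by_time[[k]]
    M <- diag(K)
    for (s in unique(g$from)) {
      ss <- as.character(s)
      y <- sum(starts[[ss]] < ut[k]) - sum(stops[[ss]] < ut[k])
      rows <- g[g$from == s, ]
      h <- rows$count / y
      M[s, rows$to] <- M[s, rows$to] + h
      M[s, s] <- M[s, s] - sum(h)
    }
    P <- P %*% M
    row0[k, ] <- P[1, ]
  }
  list(ut = ut, row0 = row0, final = P)
}

#' State occupation probabilities (Aalen-Johansen)
#'
#' Product-integral estimator of the probability of occupying each state of
#' the progressive multi-state model at time `t`, starting from diagnosis
#' at time 0: the matrix of Nelson-Aalen transition-hazard increments is
#' accumulated as a product of row-stochastic matrices over the observed
#' transition times.
#'
#' @inheritParams cci
#' @param space A [progressive_states()] object; defaults to the
#'   single-death space at the cohort's observed depth.
#' @return A tibble with columns `time`, `state` (label), `estimate`.
#' @export
occupation_probabilities <- function(histories, grid = NULL, space = NULL) {
  histories <- assert_history(histories, clock = "origin")
  r <- max(max_remission_count(histories), 1L)
  space <- space %||% progressive_states(r)
  records <- history_records(histories, space)
  aj <- aj_product(records, K = nrow(space$states))
  grid <- sort(unique(as.double(grid %||% c(0, aj$ut))))
  idx <- findInterval(grid, aj$ut)
  start <- c(1, rep(0, nrow(space$states) - 1L))
  probs <- rbind(start, aj$row0)[idx + 1L, , drop = FALSE]
  tibble(time = rep(grid, times = nrow(space$states)),
         state = rep(space$states$label, each = length(grid)),
         estimate = as.vector(probs))
}

#' Current cumulative incidence via the Markov multi-state model
#'
#' Comparator estimator: the summed Aalen-Johansen occupation
#' probabilities of all remission states of the progressive multi-state
#' model. Unlike [cci()], which combines separately estimated cumulative
#' incidence curves, this estimates the transition probability matrix
#' directly; both target the same quantity and nearly coincide while
#' enough patients remain under follow-up.
#'
#' @inheritParams cci
#' @return A tibble of class `current_curve` (`measure = "cci_markov"`).
#' @export
cci_markov <- function(histories, grid = NULL, B = 0, level = 0.95,
                       seed = NULL) {
  histories <- assert_history(histories, clock = "origin")
  r <- max(max_remission_count(histories), 1L)
  space <- progressive_states(r)
  records <- history_records(histories, space)
  grid_default <- sort(unique(c(0, records$tstop[!is.na(records$to)])))
  grid <- sort(unique(as.double(grid %||% grid_default)))
  rem_states <- space$states$index[space$states$type == "remission"]
  kernel <- function(recs) {
    aj <- aj_product(recs, K = nrow(space$states))
    idx <- findInterval(grid, aj$ut)
    vals <- c(0, rowSums(aj$row0[, rem_states, drop = FALSE]))
    vals[idx + 1L]
  }
  est <- kernel(records)
  out <- tibble(time = grid, estimate = est)
  if (B > 0) {
    recs_by_pat <- split(records, records$patient_id)
    pats <- names(recs_by_pat)
    stat <- function(idx_pat) {
      recs <- bind_rows(recs_by_pat[idx_pat])
      kernel(recs)
    }
    bands <- boot_bands_index(n = length(pats), stat = stat, grid = grid,
                              B = B, level = level, seed = seed)
    out$lower <- bands$lower
    out$upper <- bands$upper
  }
  new_current_curve(out, measure = "cci_markov",
                    n = length(unique(histories$patient_id)), r = r,
                    B = B, level = level, seed = seed)
}

#' Compare the direct and Markov estimators of the current cumulative
#' incidence
#'
#' @inheritParams cci
#' @return A tibble with columns `time`, `cci`, `cci_markov`, `difference`
#'   and `n_risk` (patients still under observation; the two estimators are
#'   known to diverge once few patients remain at risk).
#' @export
compare_markov <- function(histories, grid = NULL) {
  histories <- assert_history(histories, clock = "origin")
  direct <- cci(histories, grid = grid)
  grid <- direct$time
  mk <- cci_markov(histories, grid = grid)
  tibble(time = grid,
         cci = direct$estimate,
         cci_markov = mk$estimate,
         difference = direct$estimate - mk$estimate,
         n_risk = at_risk(histories, grid)$n_risk)
}
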