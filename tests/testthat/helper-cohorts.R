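# shared fixtures and brute-force oracles, built in code

events <- function(...) {
  rows <- list(...)
  tibble::tibble(
    patient_id = vapply(rows, `[[`, "", 1),
    time = as.double(vapply(rows, `[[`, "", 2)),
    event = vapply(rows, `[[`, "", 3)
  )
}

ev <- function(id, time, kind) c(id, as.character(time), kind)

# the two-patient worked example: A cycles through two remissions and is
# censored, B dies in first remission
toy_cohort <- function() {
  build_histories(events(
    ev("A", 1, "achieve"), ev("A", 3, "lose"),
    ev("A", 5, "achieve"), ev("A", 9, "censor"),
    ev("B", 2, "achieve"), ev("B", 4, "death")
  ))
}

# Brute-force state-occupation oracle, independent of the package kernels:
# walks each patient's raw rows and counts who is alive and in remission.
# For reset = TRUE, counts on the first-remission clock among achievers.
oracle_in_remission <- function(df, times, reset = FALSE) {
  split_pat <- split(df, df$patient_id)
  vapply(times, function(t) {
    states <- vapply(split_pat, function(p) {
      p <- p[order(p$time), ]
      tm <- p$time
      if (reset) {
        a1 <- tm[p$event == "achieve"][1]
        if (is.na(a1)) return(NA) # never achieved: excluded
        tm <- tm - a1 # shift onto the first-remission clock
      }
      dead <- any(p$event == "death" & tm <= t)
      n_a <- sum(p$event == "achieve" & tm <= t)
      n_l <- sum(p$event == "lose" & tm <= t)
      (n_a - n_l) == 1 && !dead # the first achievement sits at reset time 0
    }, NA)
    mean(states, na.rm = TRUE)
  }, 0)
}

# direct empirical survivor fraction for uncensored single-endpoint data
oracle_survivor <- function(times_obs, t) {
  vapply(t, function(u) mean(times_obs > u), 0)
}
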