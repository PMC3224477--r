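#' Event vocabulary for remission-relapse histories
#'
#' A patient history is a sequence of remission achievements (`achieve`,
#' entering the leukaemia-free state) and remission losses (`lose`,
#' cytogenetic relapse), terminated by exactly one of `death` or `censor`
#' (end of observation). Times are measured from therapy initiation
#' (the default clock origin) and carry whatever unit the data declare;
#' the package default is months.
#'
#' @keywords internal
#' @name event_vocabulary
NULL

EVENT_KINDS <- c("achieve", "lose", "death", "censor")
TERMINAL_KINDS <- c("death", "censor")

#' Read a long-format event table
#'
#' Reads a delimited file with one row per event and columns for patient id,
#' event time and event kind. Column names and the event vocabulary are
#' configurable so that files using e.g. `remission`/`relapse` labels can be
#' decoded without editing the data.
#'
#' @param file Path to a CSV/TSV file (delimiter guessed from the extension
#'   unless `delim` is given).
#' @param cols Named character vector mapping the roles `patient_id`, `time`
#'   and `event` to column names in the file.
#' @param event_map Optional named character vector mapping labels found in
#'   the file to the canonical vocabulary `achieve`, `lose`, `death`,
#'   `censor`; canonical labels are always accepted.
#' @param delim Field delimiter; default `","` (or `"\t"` for `.tsv` files).
#'
#' @return A tibble with columns `patient_id`, `time`, `event`, one row per
#'   input row in file order. No cohort-level validation is performed; pass
#'   the result to [as_event_history()].
#' @export
read_long_events <- function(file,
                             cols = c(patient_id = "patient_id",
                                      time = "time",
                                      event = "event"),
                             event_map = NULL,
                             delim = NULL) {
  delim <- delim %||% if (grepl("\\.tsv$", file, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(file, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  needed <- c("patient_id", "time", "event")
  cols <- c(cols)
  for (role in needed) {
    nm <- cols[[role]] %||% role
    if (!nm %in% names(raw)) {
      abort(sprintf("Input is missing the `%s` column (mapped role: %s).", nm, role))
    }
  }
  out <- tibble(
    patient_id = as.character(raw[[cols[["patient_id"]]]]),
    time = suppressWarnings(as.double(raw[[cols[["time"]]]])),
    event = as.character(raw[[cols[["event"]]]])
  )
  bad_time <- which(is.na(out$time))
  if (length(bad_time)) {
    abort(sprintf("Unparseable time value in row(s): %s.",
                  paste(utils::head(bad_time, 5), collapse = ", ")))
  }
  if (!is.null(event_map)) {
    hit <- out$event %in% names(event_map)
    out$event[hit] <- unname(event_map[out$event[hit]])
  }
  bad_kind <- which(!out$event %in% EVENT_KINDS)
  if (length(bad_kind)) {
    abort(sprintf("Unknown event kind %s in row(s): %s.",
                  paste(unique(out$event[bad_kind]), collapse = "/"),
                  paste(utils::head(bad_kind, 5), collapse = ", ")))
  }
  out
}

#' Validate a cohort of remission-relapse histories
#'
#' Checks the structural invariants of a long-format event table and returns
#' it as a validated `event_history` tibble, sorted by patient id and time.
#' Invariants enforced per patient:
#' * all times finite and non-negative, strictly increasing (within-patient
#'   ties are rejected rather than ordered by convention);
#' * exactly one terminal event (`death` or `censor`), occurring last;
#' * remission transitions strictly alternate, starting with `achieve` on
#'   the therapy-initiation clock (or with `lose` on the first-remission
#'   clock produced by [reset_first_remission()], where patients begin in
#'   remission).
#'
#' @param x A data frame with columns `patient_id`, `time`, `event`.
#' @param clock `"origin"` for histories timed from therapy initiation,
#'   `"first_remission"` for reset-clock histories starting in remission.
#' @return The validated tibble with class `event_history` and a `clock`
#'   attribute.
#' @export
as_event_history <- function(x, clock = c("origin", "first_remission")) {
  clock <- match.arg(clock)
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  for (nm in c("patient_id", "time", "event")) {
    if (!nm %in% names(x)) abort(sprintf("Input is missing the `%s` column.", nm))
  }
  x <- tibble(patient_id = as.character(x$patient_id),
              time = as.double(x$time),
              event = as.character(x$event))
  if (nrow(x) == 0) abort("Empty cohort: no event records.")
  if (any(!is.finite(x$time)) || any(x$time < 0)) {
    abort("Event times must be finite and non-negative.")
  }
  bad <- setdiff(unique(x$event), EVENT_KINDS)
  if (length(bad)) {
    abort(sprintf("Unknown event kind(s): %s.", paste(bad, collapse = ", ")))
  }
  x <- arrange(x, .data$patient_id, .data$time)
  first_transition <- if (clock == "origin") "achieve" else "lose"
  for (split in split(seq_len(nrow(x)), x$patient_id)) {
    pid <- x$patient_id[split[1]]
    times <- x$time[split]
    kinds <- x$event[split]
    if (anyDuplicated(times)) {
      abort(sprintf("Patient %s has tied event times; ties are invalid input.", pid))
    }
    term <- which(kinds %in% TERMINAL_KINDS)
    if (length(term) != 1) {
      abort(sprintf("Patient %s must have exactly one terminal event (death/censor), found %d.",
                    pid, length(term)))
    }
    if (term != length(kinds)) {
      abort(sprintf("Patient %s has events recorded after the terminal event.", pid))
    }
    trans <- kinds[-term]
    if (length(trans)) {
      expected <- rep_len(
        if (first_transition == "achieve") c("achieve", "lose") else c("lose", "achieve"),
        length(trans)
      )
      if (!all(trans == expected)) {
        abort(sprintf(
          "Patient %s: remission transitions must alternate %s/lose starting with `%s`.",
          pid, "achieve", first_transition))
      }
    }
  }
  attr(x, "clock") <- clock
  class(x) <- c("event_history", class(x))
  x
}

#' Build validated histories from event records
#'
#' Convenience wrapper equivalent to [as_event_history()] on the
#' therapy-initiation clock; provided so that reading and validation are
#' separate, testable steps.
#'
#' @inheritParams as_event_history
#' @return A validated `event_history` tibble sorted by patient id.
#' @export
build_histories <- function(x) {
  as_event_history(x, clock = "origin")
}

assert_history <- function(histories, clock = NULL) {
  if (!inherits(histories, "event_history")) {
    histories <- as_event_history(histories, clock = clock %||% "origin")
  } else if (!is.null(clock) && !identical(attr(histories, "clock"), clock)) {
    abort(sprintf("Expected histories on the `%s` clock.", clock))
  }
  histories
}

#' Maximum remission depth of a cohort
#'
#' The largest number of remission achievements observed for any patient;
#' this drives how many component curves the current-survival estimators
#' need. It depends mainly on the length of follow-up.
#'
#' @param histories An `event_history` tibble.
#' @return A non-negative integer.
#' @export
max_remission_count <- function(histories) {
  histories <- assert_history(histories)
  counts <- tapply(histories$event == "achieve", histories$patient_id, sum)
  if (attr(histories, "clock") == "first_remission") {
    # patients start in remission 1, which is not recorded as a row
    counts <- counts + 1L
  }
  as.integer(max(counts))
}

#' Per-patient summaries used by the estimator kernels
#'
#' @return tibble: patient_id, achieve_times (list), lose_times (list),
#'   terminal_time, terminal_kind, in_remission_at_start
#' @noRd
history_summary <- function(histories) {
  clock <- attr(histories, "clock") %||% "origin"
  idx <- split(seq_len(nrow(histories)), histories$patient_id)
  pid <- names(idx)
  ach <- vector("list", length(idx))
  los <- vector("list", length(idx))
  tt <- numeric(length(idx))
  tk <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    kinds <- histories$event[i]
    times <- histories$time[i]
    ach[[k]] <- times[kinds == "achieve"]
    los[[k]] <- times[kinds == "lose"]
    term <- length(i)
    tt[k] <- times[term]
    tk[k] <- kinds[term]
  }
  tibble(patient_id = pid, achieve_times = ach, lose_times = los,
         terminal_time = tt, terminal_kind = tk,
         starts_in_remission = clock == "first_remission")
}

#' Paired achievement transition vectors
#'
#' For each patient and remission depth `i = 1..r`, the time to the i-th
#' remission achievement together with a cause code: `1` if the i-th
#' achievement was observed, `2` if the patient died before a possible i-th
#' achievement, `0` if censored first. All times are on the cohort clock.
#'
#' @param histories An `event_history` tibble on the therapy-initiation
#'   clock.
#' @param r Remission depth; defaults to [max_remission_count()]. May be set
#'   lower to truncate deep histories for sensitivity analyses.
#' @return A tibble with columns `patient_id`, `i`, `time`, `cause`.
#' @export
achievement_vectors <- function(histories, r = NULL) {
  histories <- assert_history(histories, clock = "origin")
  v <- cohort_vectors(histories, r = r)
  vectors_to_tibble(v$patients, v$at, v$ac, names = c("time", "cause"))
}

#' Paired loss transition vectors
#'
#' For each patient and depth `i`, the time to the i-th remission loss with
#' cause code `1` (i-th loss observed), `2` (death before the i-th loss) or
#' `0` (censored), plus a logical marker identifying, among the deaths,
#' those that occurred while in the i-th remission (after the i-th
#' achievement) -- the events counted by the death-in-remission cumulative
#' incidence component.
#'
#' @inheritParams achievement_vectors
#' @return A tibble with columns `patient_id`, `i`, `time`, `cause`,
#'   `death_in_remission`.
#' @export
loss_vectors <- function(histories, r = NULL) {
  histories <- assert_history(histories, clock = "origin")
  v <- cohort_vectors(histories, r = r)
  out <- vectors_to_tibble(v$patients, v$lt, v$lc, names = c("time", "cause"))
  out$death_in_remission <- as.vector(t(v$lrem))
  out
}

vectors_to_tibble <- function(patients, tmat, cmat, names) {
  r <- ncol(tmat)
  out <- tibble(
    patient_id = rep(patients, each = r),
    i = rep(seq_len(r), times = length(patients)),
    t = as.vector(t(tmat)),
    c = as.integer(t(cmat))
  )
  names(out)[3:4] <- names
  out
}

#' Reset the clock at the first remission
#'
#' Restricts the cohort to patients who achieved at least one remission and
#' shifts every retained event time by the patient's first achievement time.
#' The first achievement maps to time 0 and is dropped as a transition: on
#' the new clock each patient starts in remission 1, so retained transitions
#' begin with `lose`. This is the time scale on which current leukaemia-free
#' survival is defined.
#'
#' @param histories An `event_history` tibble on the therapy-initiation
#'   clock.
#' @return An `event_history` tibble with `clock = "first_remission"`.
#' @export
reset_first_remission <- function(histories) {
  histories <- assert_history(histories, clock = "origin")
  ach <- histories[histories$event == "achieve", ]
  if (nrow(ach) == 0) {
    abort("No patient achieved a remission; the first-remission clock (CLFS) is undefined.")
  }
  firsts <- ach |>
    group_by(.data$patient_id) |>
    summarise(t1 = min(.data$time), .groups = "drop")
  out <- histories |>
    dplyr::inner_join(firsts, by = "patient_id") |>
    filter(.data$time > .data$t1) |>
    mutate(time = .data$time - .data$t1) |>
    select("patient_id", "time", "event")
  as_event_history(out, clock = "first_remission")
}
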