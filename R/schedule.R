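#' Allocate event counts to stimulus types by largest-remainder rounding
#'
#' Deterministic and order-stable: exact quotas `proportions * n` are
#' floored, and the remaining events are assigned in decreasing order of
#' fractional remainder, ties broken by the order of `proportions`
#' (conventionally frequent, target, distractor).
#'
#' @param n total number of events.
#' @param proportions named numeric vector of type proportions summing to 1.
#' @return named integer vector of per-type counts summing to `n`.
#' @keywords internal
largest_remainder_counts <- function(n, proportions) {
  quota <- proportions * n
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    rem <- quota - counts
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Generate stimulus schedules for an oddball study
#'
#' Emulates a three-stimulus visual oddball design: per session,
#' `events_per_session` stimuli are presented in random order with
#' inter-stimulus intervals drawn uniformly from `isi_choices`. Type counts
#' are fixed by largest-remainder rounding of `proportions`, so every
#' session carries exactly the configured mix (defaults: 70% frequent,
#' 15% target, 15% distractor at ISIs of 4, 5 or 6 s).
#'
#' @param n_sessions number of sessions.
#' @param events_per_session number of stimuli per session.
#' @param proportions named fractions per stimulus type, summing to 1.
#' @param isi_choices candidate inter-stimulus intervals in seconds.
#' @param seed integer seed; each session uses a derived child seed.
#' @param stim_duration stimulus presentation time in seconds (0.5 s).
#' @param session_duration optional session length in seconds. When given,
#'   ISI sequences whose last stimulus would not fit inside the session are
#'   redrawn (deterministically under the seed); when `NULL`, the session
#'   duration is recorded as last onset + `max(isi_choices)`.
#' @return a list of `stim_schedule` objects (data frames with columns
#'   `onset`, `duration`, `trial_type` and attributes `session_id`,
#'   `session_duration`).
#' @export
generate_stimulus_schedule <- function(n_sessions,
                                       events_per_session,
                                       proportions = c(frequent = 0.70,
                                                       target = 0.15,
                                                       distractor = 0.15),
                                       isi_choices = c(4, 5, 6),
                                       seed = 1L,
                                       stim_duration = 0.5,
                                       session_duration = NULL) {
  if (events_per_session < 1) stopf("events_per_session must be >= 1")
  if (abs(sum(proportions) - 1) > 1e-9) {
    stopf("stimulus type proportions must sum to 1 (got %.12f)",
          sum(proportions))
  }
  if (is.null(names(proportions))) {
    stopf("proportions must be named by stimulus type")
  }
  counts <- largest_remainder_counts(events_per_session, proportions)
  lapply(seq_len(n_sessions), function(j) {
    set.seed(child_seed(seed, j))
    types <- rep(names(counts), counts)
    types <- types[sample.int(length(types))]
    n <- events_per_session
    for (try in seq_len(1000L)) {
      isi <- if (n > 1) {
        isi_choices[sample.int(length(isi_choices), n - 1,
                               replace = TRUE)]
      } else numeric(0)
      onsets <- cumsum(c(0, isi))
      if (is.null(session_duration) ||
          onsets[n] + stim_duration <= session_duration) {
        break
      }
      if (try == 1000L) {
        stopf("could not fit %d events into a %.2f s session", n,
              session_duration)
      }
    }
    sched <- data.frame(onset = onsets,
                        duration = rep(stim_duration, n),
                        trial_type = types,
                        stringsAsFactors = FALSE)
    attr(sched, "session_id") <- j
    attr(sched, "session_duration") <-
      session_duration %||% (onsets[n] + max(isi_choices))
    class(sched) <- c("stim_schedule", "data.frame")
    sched
  })
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> session %s: %d events over %.1f s (%s)\n",
              attr(x, "session_id"), nrow(x), attr(x, "session_duration"),
              paste(sprintf("%s=%d", names(table(x$trial_type)),
                            as.integer(table(x$trial_type))),
                    collapse = ", ")))
  invisible(x)
}
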