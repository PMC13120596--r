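#' Convert a transition-event log into duration-annotated bouts
#'
#' Each event opens a bout that lasts until the next event; the final
#' bout is closed at \code{stream_end}. Durations are the pairwise
#' differences of consecutive event timestamps, so the durations sum
#' exactly to \code{stream_end} minus the first event timestamp.
#'
#' @param events Data frame \code{timestamp_ms}, \code{state}, strictly
#'   increasing timestamps, consecutive states differing.
#' @param stream_end End-of-recording timestamp in ms; must not precede
#'   the last event.
#' @return Data frame with columns \code{state}, \code{start_ms},
#'   \code{end_ms}, \code{duration_s}.
#' @export
bouts_from_events <- function(events, stream_end) {
  events <- validate_events(events)
  if (stream_end < events$timestamp_ms[nrow(events)])
    stop("`stream_end` precedes the last event", call. = FALSE)
  start <- events$timestamp_ms
  end <- c(events$timestamp_ms[-1], stream_end)
  data.frame(state = events$state, start_ms = start, end_ms = end,
             duration_s = (end - start) / 1000)
}

validate_events <- function(events) {
  if (!is.data.frame(events) ||
      !all(c("timestamp_ms", "state") %in% names(events)))
    stop("events must have columns timestamp_ms, state", call. = FALSE)
  if (nrow(events) == 0L) stop("event log is empty", call. = FALSE)
  if (is.unsorted(events$timestamp_ms, strictly = TRUE))
    stop("event timestamps must be strictly increasing", call. = FALSE)
  bad <- !events$state %in% posture_states()
  if (any(bad))
    stop("unknown state(s): ", paste(unique(events$state[bad]),
                                     collapse = ", "), call. = FALSE)
  events[c("timestamp_ms", "state")]
}

#' Apply the 60-s clinical bout filter
#'
#' Stand/away bouts shorter than the clinical minimum are treated as
#' fragmentation noise, but their time is reassigned rather than deleted:
#' each internal sub-threshold stand/away bout is merged into the
#' immediately preceding retained bout (runs of consecutive sub-threshold
#' bouts accumulate into the same predecessor); a leading sub-threshold
#' bout, having no predecessor, merges forward into its successor. The
#' final bout is always retained because the recording may simply have
#' been truncated mid-bout. Sitting bouts are never filtered. When a
#' merge makes two same-state bouts adjacent they coalesce into one.
#' Total recorded time is conserved exactly.
#'
#' @param bouts Contiguous bout table as produced by
#'   \code{\link{bouts_from_events}} (each bout's end equals the next
#'   bout's start).
#' @param config A \code{\link{clinical_filter_config}}.
#' @return A filtered, still contiguous bout table spanning the same
#'   total interval.
#' @export
apply_clinical_filter <- function(bouts, config = clinical_filter_config()) {
  validate_bouts(bouts)
  n <- nrow(bouts)
  min_ms <- config$min_bout * 1000
  dur_ms <- bouts$end_ms - bouts$start_ms
  sub <- bouts$state %in% config$filtered_states & dur_ms < min_ms
  sub[n] <- FALSE  # final bout always retained (session truncation)

  kept_state <- character(0)
  kept_start <- numeric(0)
  kept_end <- numeric(0)
  lead_start <- NA_real_  # start of a leading sub-threshold run, if any
  for (i in seq_len(n)) {
    if (sub[i]) {
      if (length(kept_state) == 0L) {
        # no predecessor yet: remember the start, merge forward later
        if (is.na(lead_start)) lead_start <- bouts$start_ms[i]
      } else {
        # absorb into the preceding retained bout
        kept_end[length(kept_end)] <- bouts$end_ms[i]
      }
    } else {
      start <- bouts$start_ms[i]
      if (!is.na(lead_start)) {
        start <- lead_start
        lead_start <- NA_real_
      }
      if (length(kept_state) > 0L &&
          kept_state[length(kept_state)] == bouts$state[i]) {
        # coalesce with an adjacent same-state retained bout
        kept_end[length(kept_end)] <- bouts$end_ms[i]
      } else {
        kept_state <- c(kept_state, bouts$state[i])
        kept_start <- c(kept_start, start)
        kept_end <- c(kept_end, bouts$end_ms[i])
      }
    }
  }
  data.frame(state = kept_state, start_ms = kept_start, end_ms = kept_end,
             duration_s = (kept_end - kept_start) / 1000)
}

validate_bouts <- function(bouts) {
  required <- c("state", "start_ms", "end_ms")
  if (!is.data.frame(bouts) || !all(required %in% names(bouts)))
    stop("bouts must have columns state, start_ms, end_ms", call. = FALSE)
  if (nrow(bouts) == 0L) stop("bout table is empty", call. = FALSE)
  if (any(bouts$end_ms <= bouts$start_ms))
    stop("each bout must have positive duration", call. = FALSE)
  if (nrow(bouts) > 1L &&
      any(bouts$start_ms[-1] != bouts$end_ms[-nrow(bouts)]))
    stop("bouts must be contiguous (each start equals the previous end)",
         call. = FALSE)
  invisible(bouts)
}

#' Count desk-squat repetition cycles
#'
#' A repetition cycle is one full sit -> stand -> sit excursion. The
#' counter consumes the unfiltered transition log (the clinical filter
#' would erase the ~3 s half-bouts of a squat; it gates interventions,
#' not the classifier). The state before the first logged event is taken
#' to be sitting -- the desk squat starts from the seated working
#' posture -- so a log that opens with a stand event can complete a
#' cycle. A final stand with no returning sit is half a cycle and is
#' reported separately, not in \code{detected_cycles}. Correctness is
#' the percentage psi of scripted cycles detected:
#' \code{100 * detected / scripted}.
#'
#' @param events Unfiltered transition-event log (data frame
#'   \code{timestamp_ms}, \code{state}); may have zero rows.
#' @param scripted_cycles Number of cycles the protocol prescribed
#'   (> 0).
#' @return An object of class \code{"repetition_result"}: list with
#'   \code{detected_cycles}, \code{scripted_cycles}, \code{psi},
#'   \code{half_cycle} (logical: unterminated final stand).
#' @export
count_repetitions <- function(events, scripted_cycles) {
  if (length(scripted_cycles) != 1L || is.na(scripted_cycles) ||
      scripted_cycles <= 0)
    stop("`scripted_cycles` must be a positive count", call. = FALSE)
  detected <- 0L
  pending <- FALSE
  prev <- "sit"  # implicit seated baseline before the log begins
  if (nrow(events) > 0L) {
    events <- validate_events(events)
    for (s in events$state) {
      if (s == "stand" && prev == "sit") {
        pending <- TRUE
      } else if (s == "sit" && pending) {
        detected <- detected + 1L
        pending <- FALSE
      } else if (s == "away") {
        pending <- FALSE
      }
      prev <- s
    }
  }
  structure(
    list(detected_cycles = detected,
         scripted_cycles = as.integer(scripted_cycles),
         psi = 100 * detected / scripted_cycles,
         half_cycle = pending),
    class = "repetition_result"
  )
}

#' @export
print.repetition_result <- function(x, ...) {
  cat(sprintf("Desk-squat repetitions: %d of %d scripted cycles (psi = %.1f%%)\n",
              x$detected_cycles, x$scripted_cycles, x$psi))
  if (x$half_cycle)
    cat("  (plus one unterminated final stand: half a cycle)\n")
  invisible(x)
}
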