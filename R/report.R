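#' Restrict an alignment to one ground-truth state
#'
#' Keeps the matched pairs, missed truth events and spurious sensor
#' events belonging to one posture class, with per-class raw event
#' counts, so sensitivity, delay thresholds and error summaries can be
#' reported per state.
#'
#' @param alignment An \code{\link{align_events}} result.
#' @param state One of \code{"sit"}, \code{"stand"}, \code{"away"}.
#' @return An \code{"event_alignment"} restricted to the class.
#' @export
subset_alignment <- function(alignment, state) {
  state <- match.arg(state, posture_states())
  structure(
    list(
      pairs = alignment$pairs[alignment$pairs$truth_state == state, ,
                              drop = FALSE],
      missed_truth = alignment$missed_truth[
        alignment$missed_truth$state == state, , drop = FALSE],
      spurious_sensor = alignment$spurious_sensor[
        alignment$spurious_sensor$state == state, , drop = FALSE],
      n_sensor = sum(alignment$pairs$sensor_state == state) +
        sum(alignment$spurious_sensor$state == state),
      n_truth = sum(alignment$pairs$truth_state == state) +
        sum(alignment$missed_truth$state == state)
    ),
    class = "event_alignment"
  )
}

#' Pool per-user alignments
#'
#' Concatenates matched pairs, missed and spurious events across users
#' and sums the raw counts, yielding one alignment object over which
#' pooled sensitivity and error statistics can be computed.
#'
#' @param alignments List of \code{\link{align_events}} results.
#' @return A pooled \code{"event_alignment"}.
#' @export
pool_alignments <- function(alignments) {
  structure(
    list(
      pairs = do.call(rbind, lapply(alignments, `[[`, "pairs")),
      missed_truth = do.call(rbind, lapply(alignments, `[[`,
                                           "missed_truth")),
      spurious_sensor = do.call(rbind, lapply(alignments, `[[`,
                                              "spurious_sensor")),
      n_sensor = sum(vapply(alignments, `[[`, 0L, "n_sensor")),
      n_truth = sum(vapply(alignments, `[[`, 0L, "n_truth"))
    ),
    class = "event_alignment"
  )
}

#' Full criterion-validation report for one sensor/truth log pair
#'
#' Orchestrates the whole validation chain for one recording: greedy
#' event alignment, per-state sensitivity curves and minimum delay
#' thresholds, duration error summaries over temporally matched events,
#' the one-vs-rest confusion matrix and class metrics, and Bland-Altman
#' agreement of matched bout durations (pairs within the hard tolerance
#' cap delta_T).
#'
#' @param sensor_events,truth_events Transition-event logs (data frames
#'   \code{timestamp_ms}, \code{state}).
#' @param stream_end Timestamp (ms) closing the final bout of both logs;
#'   defaults to the latest event timestamp (giving the final event a
#'   zero-length bout that drops out of duration pairing).
#' @param config A \code{\link{validation_config}}.
#' @param allow_partial If \code{TRUE}, per-state blocks whose metrics
#'   are undefined (e.g. no matched events) are reported as \code{NULL}
#'   instead of failing.
#' @return An object of class \code{"validation_report"}: list with
#'   \code{alignment}, \code{per_state} (each with \code{curve},
#'   \code{delta_min}, \code{errors}), \code{confusion},
#'   \code{class_metrics}, \code{agreement}.
#' @export
validation_report <- function(sensor_events, truth_events,
                              stream_end = NULL,
                              config = validation_config(),
                              allow_partial = FALSE) {
  if (is.null(stream_end))
    stream_end <- max(sensor_events$timestamp_ms,
                      truth_events$timestamp_ms)
  alignment <- align_events(sensor_events, truth_events)
  sensor_bouts <- bouts_from_events(sensor_events, stream_end)
  truth_bouts <- bouts_from_events(truth_events, stream_end)

  states <- intersect(posture_states(), unique(truth_events$state))
  per_state <- lapply(states, function(s) {
    sub <- subset_alignment(alignment, s)
    block <- tryCatch({
      curve <- find_delta_min(sub, config)
      errors <- duration_errors(sensor_bouts, truth_bouts, sub,
                                curve$delta_min)
      list(curve = curve, delta_min = curve$delta_min, errors = errors)
    }, error = function(e) {
      if (allow_partial) NULL else stop(e)
    })
    block
  })
  names(per_state) <- states

  cm <- build_confusion(alignment)
  cls <- lapply(states, function(s) class_metrics(cm, s))
  names(cls) <- states

  used <- alignment$pairs[alignment$pairs$delta_s <= config$max_tolerance,
                          , drop = FALSE]
  sd_min <- bout_duration_at(sensor_bouts, used$sensor_ms) / 60
  gd_min <- bout_duration_at(truth_bouts, used$truth_ms) / 60
  keep <- !is.na(sd_min) & !is.na(gd_min)
  agreement <- tryCatch(bland_altman(sd_min[keep], gd_min[keep]),
                        error = function(e) if (allow_partial) NULL
                                            else stop(e))

  structure(
    list(alignment = alignment, per_state = per_state, confusion = cm,
         class_metrics = cls, agreement = agreement,
         stream_end = stream_end, config = config),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Criterion-validation report\n")
  print(x$alignment)
  for (s in names(x$per_state)) {
    blk <- x$per_state[[s]]
    if (is.null(blk)) {
      cat(sprintf("  %-5s: metrics undefined\n", s))
      next
    }
    e <- blk$errors
    cat(sprintf(
      "  %-5s: sensitivity %.1f%% at delta_min %g s | MAE %.2f s | count bias %+d\n",
      s, sensitivity_at(subset_alignment(x$alignment, s), blk$delta_min),
      blk$delta_min, e$mae, e$count_bias))
  }
  cat("\n")
  print(x$confusion)
  for (s in names(x$class_metrics)) print(x$class_metrics[[s]])
  if (!is.null(x$agreement)) print(x$agreement)
  invisible(x)
}

#' Serialise a validation report to JSON
#'
#' Writes one record per posture state mirroring the columns of a
#' duration/event-detection performance table (mean difference with CI,
#' MAE with SD, sensitivity at delta_min, delta_min, count bias), the
#' per-class one-vs-rest metrics rounded to two decimals, and the
#' agreement block.
#'
#' @param report A \code{\link{validation_report}}.
#' @param path Output file; \code{NULL} returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
write_report <- function(report, path = NULL) {
  per_state <- lapply(names(report$per_state), function(s) {
    blk <- report$per_state[[s]]
    if (is.null(blk)) return(list(state = s, undefined = TRUE))
    e <- blk$errors
    list(
      state = s,
      mean_diff_min = e$mean_diff,
      ci95_min = c(e$ci95_lower, e$ci95_upper),
      mae_s = e$mae, mae_sd_s = e$mae_sd,
      sensitivity_pct = sensitivity_at(
        subset_alignment(report$alignment, s), blk$delta_min),
      delta_min_s = blk$delta_min,
      count_bias = e$count_bias
    )
  })
  cls <- lapply(report$class_metrics, function(m)
    list(state = m$state,
         precision = round(m$precision, 2), recall = round(m$recall, 2),
         specificity = round(m$specificity, 2), f1 = round(m$f1, 2)))
  agr <- if (is.null(report$agreement)) NULL else {
    a <- report$agreement
    list(mean_bias_min = a$mean_bias, loa_half_width_min = a$loa_half_width,
         loa_min = c(a$loa_lower, a$loa_upper),
         slope = a$slope, slope_p = a$slope_p, n = a$n)
  }
  obj <- list(duration_detection = per_state,
              classification = unname(cls),
              agreement = agr,
              confusion = report$confusion$table)
  if (is.null(path))
    return(invisible(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                      digits = NA, null = "null")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Simulate, classify and validate a whole protocol session
#'
#' The end-to-end desk study in one call: simulate streams for a panel
#' of participants, run the differential distance classifier on each,
#' align sensor transitions with the scripted ground truth, and pool
#' the validation statistics. For the squat protocol the repetition
#' counter is also run on each participant's unfiltered transitions.
#'
#' @inheritParams simulate_participants
#' @param vconfig A \code{\link{validation_config}}.
#' @return An object of class \code{"protocol_study"}: list with
#'   \code{participants} (per-user list of simulation, classifier and
#'   alignment results), \code{report} (pooled
#'   \code{\link{validation_report}}-shaped object), \code{per_user}
#'   (\code{\link{per_user_mae}} table, using the pooled sit-state
#'   delta_min... ), and for P3 \code{repetitions} (pooled
#'   \code{\link{count_repetitions}} result).
#' @export
run_protocol_study <- function(protocol_id, n_participants = 7,
                               noise = noise_free(),
                               config = ddc_config(),
                               vconfig = validation_config(), seed = 1) {
  sims <- simulate_participants(protocol_id, n_participants,
                                noise = noise, config = config,
                                seed = seed)
  participants <- lapply(sims, function(sim) {
    fit <- ddc(sim$stream, config)
    alignment <- align_events(fit$events, sim$truth)
    end_ms <- sim$stream$timestamp_ms[nrow(sim$stream)]
    list(sim = sim, fit = fit, alignment = alignment,
         sensor_bouts = bouts_from_events(fit$events, end_ms),
         truth_bouts = bouts_from_events(sim$truth, end_ms))
  })
  all_sensor <- do.call(rbind, lapply(seq_along(participants), function(i) {
    ev <- participants[[i]]$fit$events
    ev$timestamp_ms <- ev$timestamp_ms + (i - 1) * 1e9  # keep users apart
    ev
  }))
  all_truth <- do.call(rbind, lapply(seq_along(participants), function(i) {
    ev <- participants[[i]]$sim$truth
    ev$timestamp_ms <- ev$timestamp_ms + (i - 1) * 1e9
    ev
  }))
  report <- validation_report(all_sensor, all_truth,
                              stream_end = max(all_sensor$timestamp_ms,
                                               all_truth$timestamp_ms) +
                                1000,
                              config = vconfig, allow_partial = TRUE)
  sit_dm <- if (!is.null(report$per_state$sit))
    report$per_state$sit$delta_min else vconfig$max_tolerance
  per_user <- per_user_mae(
    lapply(participants, function(p)
      list(sensor_bouts = p$sensor_bouts, truth_bouts = p$truth_bouts,
           alignment = p$alignment)),
    delta_min = sit_dm
  )
  reps <- NULL
  if (protocol_id == "P3") {
    detected <- vapply(participants, function(p)
      count_repetitions(p$fit$events,
                        nrow(p$sim$script$actions) / 2)$detected_cycles,
      integer(1))
    scripted <- vapply(participants, function(p)
      as.integer(nrow(p$sim$script$actions) / 2), integer(1))
    reps <- structure(
      list(detected_cycles = sum(detected),
           scripted_cycles = sum(scripted),
           psi = 100 * sum(detected) / sum(scripted),
           half_cycle = FALSE),
      class = "repetition_result"
    )
  }
  structure(
    list(protocol_id = protocol_id, participants = participants,
         report = report, per_user = per_user, repetitions = reps),
    class = "protocol_study"
  )
}

#' @export
print.protocol_study <- function(x, ...) {
  cat(sprintf("Simulated protocol study: %s, %d participants\n\n",
              x$protocol_id, length(x$participants)))
  print(x$report)
  if (!is.null(x$repetitions)) print(x$repetitions)
  cat("\nPer-user MAE (s):\n")
  print(x$per_user, row.names = FALSE)
  cat(sprintf("  pooled MAE: %.2f s\n", attr(x$per_user, "pooled_mae")))
  invisible(x)
}
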