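#' Align sensor events with ground-truth events
#'
#' Pairs each sensor-detected transition with its nearest-neighbour
#' ground-truth counterpart by a globally greedy rule: among all
#' still-unmatched (sensor, truth) pairs, repeatedly match the pair with
#' the smallest absolute time difference, breaking ties toward the
#' earlier truth event (then the earlier sensor event). Matching
#' continues until one log is exhausted, so a tolerance is NOT applied
#' here -- sensitivity thresholds come later
#' (\code{\link{sensitivity_at}}). Truth events left unmatched were
#' missed by the sensor; sensor events left unmatched are spurious.
#'
#' @param sensor,truth Transition-event logs (data frames
#'   \code{timestamp_ms}, \code{state}), time-sorted. Either may be
#'   empty (zero rows), in which case everything on the other side is
#'   unmatched.
#' @return An object of class \code{"event_alignment"}: list with
#'   \describe{
#'     \item{pairs}{data frame \code{sensor_ms}, \code{truth_ms},
#'       \code{sensor_state}, \code{truth_state}, \code{delta_s}}
#'     \item{missed_truth}{unmatched truth events}
#'     \item{spurious_sensor}{unmatched sensor events}
#'     \item{n_sensor, n_truth}{raw event counts}
#'   }
#' @export
align_events <- function(sensor, truth) {
  sensor <- validate_events_or_empty(sensor)
  truth <- validate_events_or_empty(truth)
  ns <- nrow(sensor); nt <- nrow(truth)
  pairs <- data.frame(sensor_ms = numeric(0), truth_ms = numeric(0),
                      sensor_state = character(0),
                      truth_state = character(0), delta_s = numeric(0))
  s_free <- rep(TRUE, ns); t_free <- rep(TRUE, nt)
  if (ns > 0L && nt > 0L) {
    cost <- abs(outer(sensor$timestamp_ms, truth$timestamp_ms, "-"))
    for (k in seq_len(min(ns, nt))) {
      sub <- cost[s_free, t_free, drop = FALSE]
      m <- min(sub)
      hit <- which(sub == m, arr.ind = TRUE)
      # tie-break: earlier truth event, then earlier sensor event
      hit <- hit[order(hit[, "col"], hit[, "row"]), , drop = FALSE]
      i <- which(s_free)[hit[1, "row"]]
      j <- which(t_free)[hit[1, "col"]]
      pairs <- rbind(pairs, data.frame(
        sensor_ms = sensor$timestamp_ms[i],
        truth_ms = truth$timestamp_ms[j],
        sensor_state = sensor$state[i],
        truth_state = truth$state[j],
        delta_s = abs(sensor$timestamp_ms[i] - truth$timestamp_ms[j]) / 1000
      ))
      s_free[i] <- FALSE; t_free[j] <- FALSE
    }
    pairs <- pairs[order(pairs$truth_ms), ]
    rownames(pairs) <- NULL
  }
  structure(
    list(pairs = pairs,
         missed_truth = truth[t_free, , drop = FALSE],
         spurious_sensor = sensor[s_free, , drop = FALSE],
         n_sensor = ns, n_truth = nt),
    class = "event_alignment"
  )
}

validate_events_or_empty <- function(events) {
  if (is.null(events) || (is.data.frame(events) && nrow(events) == 0L))
    return(data.frame(timestamp_ms = numeric(0), state = character(0)))
  validate_events(events)
}

#' @export
print.event_alignment <- function(x, ...) {
  cat("Event alignment\n")
  cat(sprintf("  %d sensor vs %d truth events; %d matched pairs\n",
              x$n_sensor, x$n_truth, nrow(x$pairs)))
  cat(sprintf("  %d missed truth, %d spurious sensor events\n",
              nrow(x$missed_truth), nrow(x$spurious_sensor)))
  if (nrow(x$pairs) > 0L)
    cat(sprintf("  |delta| quartiles (s): %s\n",
                paste(signif(stats::quantile(x$pairs$delta_s), 3),
                      collapse = " / ")))
  invisible(x)
}

#' Detection sensitivity at a given tolerance
#'
#' The percentage of ground-truth transitions for which the sensor
#' produced a matched event within \code{delta} seconds:
#' \code{100 * #(pairs with |dt| <= delta) / #truth}.
#'
#' @param alignment An \code{\link{align_events}} result.
#' @param delta Tolerance in seconds, >= 0.
#' @return Sensitivity as a percentage.
#' @export
sensitivity_at <- function(alignment, delta) {
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (alignment$n_truth == 0L)
    stop("sensitivity undefined: no ground-truth events", call. = FALSE)
  100 * sum(alignment$pairs$delta_s <= delta) / alignment$n_truth
}

#' Sensitivity curve and minimum acceptable delay threshold
#'
#' Sweeps the tolerance grid, recording the sensitivity at each value,
#' and locates delta_min: the smallest grid tolerance not exceeding the
#' hard cap delta_T at which the curve has already reached its plateau,
#' i.e. no grid tolerance up to delta_T improves sensitivity by more
#' than \code{plateau_epsilon} percentage points. If the curve is still
#' rising at delta_T, delta_min falls back to delta_T with a warning:
#' larger delays would help but are operationally unacceptable.
#'
#' @param alignment An \code{\link{align_events}} result.
#' @param config A \code{\link{validation_config}}.
#' @return An object of class \code{"sensitivity_curve"}: list with
#'   \code{deltas}, \code{values} (percentages, non-decreasing) and
#'   \code{delta_min}.
#' @export
find_delta_min <- function(alignment, config = validation_config()) {
  grid <- config$delta_grid
  phi <- vapply(grid, function(d) sensitivity_at(alignment, d), numeric(1))
  capped <- grid[grid <= config$max_tolerance]
  phi_cap <- phi[grid <= config$max_tolerance]
  plateau <- max(phi_cap)
  ok <- phi_cap >= plateau - config$plateau_epsilon
  delta_min <- capped[which(ok)[1]]
  # still rising at the cap (within the cap or beyond on the grid)?
  if (delta_min == config$max_tolerance &&
      (max(phi) > plateau + config$plateau_epsilon ||
       (length(phi_cap) > 1L &&
        phi_cap[length(phi_cap)] >
          phi_cap[length(phi_cap) - 1L] + config$plateau_epsilon)))
    warning("sensitivity still rising at max_tolerance; delta_min capped ",
            "at delta_T = ", config$max_tolerance, " s", call. = FALSE)
  structure(list(deltas = grid, values = phi, delta_min = delta_min),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat("Sensitivity vs delay tolerance\n")
  print(stats::setNames(round(x$values, 1), paste0(x$deltas, "s")))
  cat(sprintf("  delta_min = %g s\n", x$delta_min))
  invisible(x)
}

#' @export
plot.sensitivity_curve <- function(x, ...) {
  plot(x$deltas, x$values, type = "b", xlab = "delay tolerance (s)",
       ylab = "sensitivity (%)", ylim = c(0, 100), ...)
  graphics::abline(v = x$delta_min, lty = 2)
  invisible(x)
}

#' Duration error summary over matched events
#'
#' Error metrics are computed exclusively over correctly identified
#' events: matched pairs whose alignment delay does not exceed
#' \code{delta_min}. Each event is compared through the duration of the
#' bout it opens: MAE is the mean of |sensor duration - truth duration|
#' in seconds (reported with the SD of the absolute errors); the mean
#' signed difference carries a normal-theory 95% confidence interval
#' (1.96 standard errors) and is reported in minutes; the count bias is
#' the raw sensor event count minus the raw truth event count --
#' negative values mean missed events.
#'
#' @param sensor_bouts,truth_bouts Bout tables derived (via
#'   \code{\link{bouts_from_events}}) from the same logs used for the
#'   alignment.
#' @param alignment The \code{\link{align_events}} result for those logs.
#' @param delta_min Tolerance in seconds; pairs with larger delay are
#'   excluded.
#' @return An object of class \code{"error_summary"}: list with
#'   \code{mae} and \code{mae_sd} (s), \code{mean_diff},
#'   \code{ci95_half}, \code{ci95_lower}, \code{ci95_upper} (min),
#'   \code{count_bias}, \code{n}.
#' @export
duration_errors <- function(sensor_bouts, truth_bouts, alignment,
                            delta_min) {
  used <- alignment$pairs[alignment$pairs$delta_s <= delta_min, ,
                          drop = FALSE]
  if (nrow(used) == 0L)
    stop("no matched events within delta_min; error metrics undefined",
         call. = FALSE)
  sd_i <- bout_duration_at(sensor_bouts, used$sensor_ms)
  gd_i <- bout_duration_at(truth_bouts, used$truth_ms)
  keep <- !is.na(sd_i) & !is.na(gd_i)
  d <- sd_i[keep] - gd_i[keep]
  n <- length(d)
  if (n == 0L)
    stop("no matched events map to bouts; error metrics undefined",
         call. = FALSE)
  mean_diff_min <- mean(d) / 60
  se_min <- if (n > 1L) stats::sd(d) / sqrt(n) / 60 else NA_real_
  half <- 1.96 * se_min
  structure(
    list(mae = mean(abs(d)),
         mae_sd = if (n > 1L) stats::sd(abs(d)) else NA_real_,
         mean_diff = mean_diff_min,
         ci95_half = half,
         ci95_lower = mean_diff_min - half,
         ci95_upper = mean_diff_min + half,
         count_bias = alignment$n_sensor - alignment$n_truth,
         n = n),
    class = "error_summary"
  )
}

# Duration (s) of the bout opened at each given event timestamp; NA when
# the timestamp opens no bout (e.g. the event closed the recording).
bout_duration_at <- function(bouts, timestamps_ms) {
  idx <- match(timestamps_ms, bouts$start_ms)
  bouts$duration_s[idx]
}

#' @export
print.error_summary <- function(x, ...) {
  cat("Duration error summary (matched events)\n")
  cat(sprintf("  n matched        : %d\n", x$n))
  cat(sprintf("  MAE              : %.2f s (SD %.2f)\n", x$mae, x$mae_sd))
  cat(sprintf("  mean difference  : %.2f min [%.2f, %.2f]\n",
              x$mean_diff, x$ci95_lower, x$ci95_upper))
  cat(sprintf("  count bias       : %+d\n", x$count_bias))
  invisible(x)
}

#' Per-user mean absolute duration error
#'
#' Stratifies the MAE by participant: for user u,
#' \code{MAE_u = (1/n_u) * sum |S_uj - G_uj|} over that user's matched
#' events within \code{delta_min}. The pooled MAE equals the
#' event-weighted mean of the per-user values. A user with no matched
#' events is reported with \code{mae_u = NA} and flagged.
#'
#' @param per_user Named list, one element per user, each a list with
#'   elements \code{sensor_bouts}, \code{truth_bouts}, \code{alignment}.
#' @param delta_min Tolerance in seconds.
#' @return Data frame \code{user_id}, \code{mae_u}, \code{n_u},
#'   \code{undefined}; attribute \code{pooled_mae}.
#' @export
per_user_mae <- function(per_user, delta_min) {
  if (length(per_user) == 0L) stop("need at least one user", call. = FALSE)
  ids <- names(per_user)
  if (is.null(ids)) ids <- as.character(seq_along(per_user))
  rows <- lapply(seq_along(per_user), function(k) {
    u <- per_user[[k]]
    es <- tryCatch(
      duration_errors(u$sensor_bouts, u$truth_bouts, u$alignment, delta_min),
      error = function(e) NULL
    )
    if (is.null(es))
      data.frame(user_id = ids[k], mae_u = NA_real_, n_u = 0L,
                 undefined = TRUE)
    else
      data.frame(user_id = ids[k], mae_u = es$mae, n_u = es$n,
                 undefined = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !out$undefined
  attr(out, "pooled_mae") <-
    sum(out$mae_u[ok] * out$n_u[ok]) / sum(out$n_u[ok])
  out
}
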