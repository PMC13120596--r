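#' Build the posture confusion matrix from an event alignment
#'
#'
#' Every ground-truth event contributes one count, so the grand total of
#' the table equals the number of scripted events and row sums equal the
#' scripted per-class totals. A matched pair contributes
#' (truth state -> sensor state). A truth event the sensor missed is not
#' dropped: it is attributed to the sensor's prevailing state at that
#' moment (the state of the last sensor event at or before the truth
#' timestamp), which is exactly what an observer reading the sensor log
#' would have believed the user was doing. Spurious sensor events do not
#' enter the table; they surface in the count bias instead.
#'
#' @param alignment An \code{\link{align_events}} result whose event
#'   logs carried states.
#' @return An object of class \code{"posture_confusion"}: list with
#'   \code{table} (3x3 truth x sensor counts) and \code{per_class}
#'   (data frame of tp, fp, fn, tn per state).
#' @export
build_confusion <- function(alignment) {
  lev <- posture_states()
  tab <- matrix(0L, 3, 3, dimnames = list(truth = lev, sensor = lev))
  p <- alignment$pairs
  if (nrow(p) > 0L) {
    bad <- !(p$sensor_state %in% lev & p$truth_state %in% lev)
    if (any(bad)) stop("state outside {sit, stand, away}", call. = FALSE)
    for (k in seq_len(nrow(p)))
      tab[p$truth_state[k], p$sensor_state[k]] <-
        tab[p$truth_state[k], p$sensor_state[k]] + 1L
  }
  miss <- alignment$missed_truth
  if (nrow(miss) > 0L) {
    # the sensor's state timeline, from its full event log
    sensor_log <- rbind(
      p[, c("sensor_ms", "sensor_state")],
      stats::setNames(alignment$spurious_sensor,
                      c("sensor_ms", "sensor_state"))
    )
    sensor_log <- sensor_log[order(sensor_log$sensor_ms), , drop = FALSE]
    for (k in seq_len(nrow(miss))) {
      prevailing <- sensor_state_at(sensor_log, miss$timestamp_ms[k])
      tab[miss$state[k], prevailing] <- tab[miss$state[k], prevailing] + 1L
    }
  }
  total <- sum(tab)
  per_class <- do.call(rbind, lapply(lev, function(cl) {
    tp <- tab[cl, cl]
    fp <- sum(tab[, cl]) - tp
    fn <- sum(tab[cl, ]) - tp
    data.frame(state = cl, tp = tp, fp = fp, fn = fn,
               tn = total - tp - fp - fn)
  }))
  structure(list(table = tab, per_class = per_class),
            class = "posture_confusion")
}

# State of the last sensor event at or before t; the first sensor state
# when t precedes the whole log, "away" for an empty log (vacant desk).
sensor_state_at <- function(sensor_log, t_ms) {
  if (nrow(sensor_log) == 0L) return("away")
  idx <- findInterval(t_ms, sensor_log$sensor_ms)
  sensor_log$sensor_state[max(idx, 1L)]
}

#' @export
print.posture_confusion <- function(x, ...) {
  cat("Posture confusion matrix (truth rows x sensor columns)\n")
  print(x$table)
  invisible(x)
}

#' One-vs-rest classification metrics for one posture class
#'
#' Binarises the confusion matrix for the target state and computes
#' precision TP/(TP+FP), recall TP/(TP+FN), specificity TN/(TN+FP) and
#' the F1 score (harmonic mean of precision and recall), all as
#' percentages. An undefined ratio (denominator 0) yields \code{NaN}
#' with the \code{undefined} flag set rather than a silent 0.
#'
#' @param cm A \code{\link{build_confusion}} result.
#' @param class One of \code{"sit"}, \code{"stand"}, \code{"away"}.
#' @return An object of class \code{"class_metrics"}: list with
#'   \code{precision}, \code{recall}, \code{specificity}, \code{f1}
#'   (percentages), \code{undefined} (character vector of metrics with a
#'   zero denominator).
#' @examples
#' # Worked example: 13 true positives, 3 false positives, 1 false
#' # negative out of 119 events gives 81.25% precision.
#' @export
class_metrics <- function(cm, class) {
  class <- match.arg(class, posture_states())
  row <- cm$per_class[cm$per_class$state == class, ]
  ratio <- function(num, den) if (den == 0) NaN else 100 * num / den
  precision <- ratio(row$tp, row$tp + row$fp)
  recall <- ratio(row$tp, row$tp + row$fn)
  specificity <- ratio(row$tn, row$tn + row$fp)
  f1 <- if (is.nan(precision) || is.nan(recall) ||
            (precision + recall) == 0) NaN
        else 2 * precision * recall / (precision + recall)
  undefined <- c("precision", "recall", "specificity", "f1")[
    is.nan(c(precision, recall, specificity, f1))]
  structure(
    list(state = class, precision = precision, recall = recall,
         specificity = specificity, f1 = f1, undefined = undefined),
    class = "class_metrics"
  )
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("One-vs-rest metrics for '%s'\n", x$state))
  cat(sprintf("  precision %6.2f%%  recall %6.2f%%  specificity %6.2f%%  F1 %6.2f%%\n",
              x$precision, x$recall, x$specificity, x$f1))
  if (length(x$undefined))
    cat("  undefined (0/0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
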