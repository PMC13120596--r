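#' Moving-average smoothing of a distance stream
#'
#' Applies a trailing arithmetic-mean filter of length \code{window} to
#' both distance channels. Sample \code{i} of the output is the mean of
#' raw samples \code{max(1, i - window + 1) .. i}, so the first
#' \code{window - 1} samples use a partial, growing window and the output
#' is index-aligned with the input. This suppresses single-sample dropout
#' spikes: a one-sample excursion of height h moves the smoothed value by
#' only h / window.
#'
#' @param stream A data frame with columns \code{timestamp_ms},
#'   \code{torso_mm}, \code{head_mm}; timestamps strictly increasing.
#' @param config A \code{\link{ddc_config}}.
#' @return A data frame of the same shape with smoothed distances.
#' @export
smooth_stream <- function(stream, config = ddc_config()) {
  stream <- validate_stream(stream)
  data.frame(
    timestamp_ms = stream$timestamp_ms,
    torso_mm = trailing_mean(stream$torso_mm, config$window),
    head_mm = trailing_mean(stream$head_mm, config$window)
  )
}

# Trailing windowed mean with growing warm-up window, O(n) via cumsum.
trailing_mean <- function(x, window) {
  n <- length(x)
  cs <- cumsum(x)
  if (window >= n) return(cs / seq_len(n))
  lag <- c(rep(0, window), cs[seq_len(n - window)])
  width <- pmin(seq_len(n), window)
  (cs - lag) / width
}

validate_stream <- function(stream) {
  required <- c("timestamp_ms", "torso_mm", "head_mm")
  if (!is.data.frame(stream) || !all(required %in% names(stream)))
    stop("stream must be a data frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  if (nrow(stream) == 0L)
    stop("stream is empty", call. = FALSE)
  if (is.unsorted(stream$timestamp_ms, strictly = TRUE))
    stop("stream timestamps must be strictly increasing", call. = FALSE)
  if (any(stream$torso_mm < 0) || any(stream$head_mm < 0))
    stop("distances must be non-negative", call. = FALSE)
  stream[required]
}

#' Classify a single smoothed sample
#'
#' The decision tree of the differential distance classifier. A channel
#' is "detected" when its (smoothed) distance lies inside the gate
#' \code{[range_min, range_max]}, inclusive. Torso detected alone means
#' the user is seated below the head sensor's line; both detected means
#' the user stands with the torso and head in view; neither means the
#' desk is vacant.
#'
#' The fourth combination -- head detected without the torso -- is
#' geometrically implausible and treated as transient noise: the previous
#' state is held (\code{"away"} when there is none) and a warning is
#' issued.
#'
#' @param torso_mm,head_mm Smoothed distances in mm.
#' @param previous Previous posture state, or \code{NULL} at stream start.
#' @param config A \code{\link{ddc_config}}.
#' @return One of \code{"sit"}, \code{"stand"}, \code{"away"}.
#' @examples
#' classify_sample(700, 8191)   # sit
#' classify_sample(700, 1500)   # stand
#' classify_sample(8191, 8191)  # away
#' @export
classify_sample <- function(torso_mm, head_mm, previous = NULL,
                            config = ddc_config()) {
  if (torso_mm < 0 || head_mm < 0)
    stop("distances must be non-negative", call. = FALSE)
  in_gate <- function(d) d >= config$range_min & d <= config$range_max
  torso_in <- in_gate(torso_mm)
  head_in <- in_gate(head_mm)
  if (torso_in && !head_in) return("sit")
  if (torso_in && head_in) return("stand")
  if (!torso_in && !head_in) return("away")
  warning("head detected without torso; holding previous state",
          call. = FALSE)
  if (is.null(previous)) "away" else previous
}

#' Classify a raw distance stream
#'
#' Runs the full differential distance classifier: trailing moving-average
#' smoothing of both channels, then the per-sample decision tree with a
#' running previous state. One state is emitted per input sample.
#'
#' @inheritParams smooth_stream
#' @return An object of class \code{"ddc"}: a list with
#'   \describe{
#'     \item{states}{data frame \code{timestamp_ms}, \code{state}, one row
#'       per input sample}
#'     \item{events}{transition-event log, see
#'       \code{\link{extract_transitions}}}
#'     \item{config}{the configuration used}
#'   }
#' @seealso \code{\link{classify_sample}}, \code{\link{extract_transitions}}
#' @export
ddc <- function(stream, config = ddc_config()) {
  smoothed <- smooth_stream(stream, config)
  n <- nrow(smoothed)
  torso_in <- smoothed$torso_mm >= config$range_min &
    smoothed$torso_mm <= config$range_max
  head_in <- smoothed$head_mm >= config$range_min &
    smoothed$head_mm <= config$range_max
  # Vectorised decision tree; only the head-without-torso branch needs
  # the running previous state.
  state <- character(n)
  state[torso_in & !head_in] <- "sit"
  state[torso_in & head_in] <- "stand"
  state[!torso_in & !head_in] <- "away"
  hold <- which(!torso_in & head_in)
  if (length(hold) > 0L) {
    warning(sprintf(
      "head detected without torso at %d sample(s); holding previous state",
      length(hold)), call. = FALSE)
    prev <- "away"
    for (i in seq_len(n)) {
      if (state[i] == "") state[i] <- prev else prev <- state[i]
    }
  }
  states <- data.frame(timestamp_ms = smoothed$timestamp_ms, state = state)
  structure(
    list(states = states, events = extract_transitions(states),
         config = config),
    class = "ddc"
  )
}

#' @export
print.ddc <- function(x, ...) {
  n <- nrow(x$states)
  dur <- (x$states$timestamp_ms[n] - x$states$timestamp_ms[1]) / 1000
  cat("Differential distance classifier output\n")
  cat(sprintf("  %d samples spanning %.1f s; %d transition events\n",
              n, dur, nrow(x$events)))
  tab <- table(factor(x$states$state, levels = posture_states()))
  cat("  per-sample state counts:\n")
  print(tab)
  invisible(x)
}

#' @export
summary.ddc <- function(object, ...) {
  bouts <- bouts_from_events(
    object$events,
    stream_end = object$states$timestamp_ms[nrow(object$states)]
  )
  agg <- tapply(bouts$duration_s, factor(bouts$state, posture_states()), sum)
  agg[is.na(agg)] <- 0
  out <- list(bouts = bouts, total_s = agg, n_events = nrow(object$events))
  class(out) <- "summary.ddc"
  out
}

#' @export
print.summary.ddc <- function(x, ...) {
  cat("Posture summary\n")
  cat(sprintf("  transition events : %d\n", x$n_events))
  cat(sprintf("  bouts             : %d\n", nrow(x$bouts)))
  for (s in names(x$total_s))
    cat(sprintf("  total %-5s time  : %.1f s\n", s, x$total_s[[s]]))
  invisible(x)
}

#' @export
plot.ddc <- function(x, ...) {
  st <- x$states
  lev <- posture_states()
  y <- match(st$state, lev)
  t_s <- (st$timestamp_ms - st$timestamp_ms[1]) / 1000
  plot(t_s, y, type = "s", yaxt = "n", xlab = "time (s)",
       ylab = "posture state", ylim = c(0.5, 3.5), ...)
  graphics::axis(2, at = 1:3, labels = lev)
  invisible(x)
}

#' Extract transition events from a state sequence
#'
#' Reduces a per-sample state sequence to its change points: the first
#' sample always yields an initial event; thereafter an event is emitted
#' exactly when the state differs from the previous sample, so the event
#' count is the number of state changes plus one.
#'
#' @param states Data frame with columns \code{timestamp_ms},
#'   \code{state}.
#' @return Data frame \code{timestamp_ms}, \code{state}: the transition
#'   event log.
#' @export
extract_transitions <- function(states) {
  if (!is.data.frame(states) ||
      !all(c("timestamp_ms", "state") %in% names(states)))
    stop("states must have columns timestamp_ms, state", call. = FALSE)
  if (nrow(states) == 0L) stop("states is empty", call. = FALSE)
  keep <- c(TRUE, states$state[-1] != states$state[-nrow(states)])
  out <- states[keep, c("timestamp_ms", "state")]
  rownames(out) <- NULL
  out
}
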