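#' Classifier configuration
#'
#' Operating parameters of the differential distance classifier: the
#' moving-average window, the detection range gate, the sensor saturation
#' code and the sampling period.
#'
#' @param window Moving-average window length in samples (omega). The
#'   smoother uses a trailing window; the first \code{window - 1} samples
#'   use a partial (growing) window so the smoothed stream stays
#'   index-aligned with the raw stream.
#' @param range_min Lower edge of the detection gate in mm. A channel is
#'   "detected" when its smoothed distance lies in
#'   \code{[range_min, range_max]}, both ends inclusive.
#' @param range_max Upper edge of the detection gate in mm.
#' @param sensor_max Saturation code of the sensor in mm, returned when
#'   nothing reflects within range.
#' @param sample_period Sampling period in seconds (3.3 Hz = 0.3 s).
#'
#' @return An object of class \code{"ddc_config"}: a validated list with
#'   the five fields above.
#' @examples
#' ddc_config()
#' ddc_config(window = 4)
#' @export
ddc_config <- function(window = 8, range_min = 300, range_max = 2000,
                       sensor_max = 8191, sample_period = 0.3) {
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L)
    stop("`window` must be a single integer >= 1", call. = FALSE)
  if (sample_period <= 0)
    stop("`sample_period` must be positive", call. = FALSE)
  if (!(range_min < range_max && range_max < sensor_max))
    stop("need range_min < range_max < sensor_max", call. = FALSE)
  structure(
    list(window = window, range_min = range_min, range_max = range_max,
         sensor_max = sensor_max, sample_period = sample_period),
    class = "ddc_config"
  )
}

#' @export
print.ddc_config <- function(x, ...) {
  cat("Differential distance classifier configuration\n")
  cat(sprintf("  window (omega) : %d samples (%.1f s)\n",
              x$window, x$window * x$sample_period))
  cat(sprintf("  detection gate : [%g, %g] mm\n", x$range_min, x$range_max))
  cat(sprintf("  sensor maximum : %g mm\n", x$sensor_max))
  cat(sprintf("  sample period  : %g s (%.1f Hz)\n",
              x$sample_period, 1 / x$sample_period))
  invisible(x)
}

#' Clinical bout-filter configuration
#'
#' The minimum-duration filter reflects clinical evidence that activity
#' bouts need to last about a minute to be cardiometabolically
#' meaningful: stand/away bouts shorter than \code{min_bout} are not
#' deleted but merged, time-conservingly, into a neighbouring retained
#' bout (see \code{\link{apply_clinical_filter}}).
#'
#' @param min_bout Minimum retained bout duration in seconds.
#' @param filtered_states States subject to the filter; sitting is never
#'   filtered.
#' @return An object of class \code{"clinical_filter_config"}.
#' @export
clinical_filter_config <- function(min_bout = 60,
                                   filtered_states = c("stand", "away")) {
  if (min_bout <= 0) stop("`min_bout` must be positive", call. = FALSE)
  filtered_states <- match.arg(filtered_states, posture_states(),
                               several.ok = TRUE)
  structure(list(min_bout = min_bout, filtered_states = filtered_states),
            class = "clinical_filter_config")
}

#' Validation configuration
#'
#' Parameters of the temporal-tolerance analysis: the hard cap on the
#' acceptable detection delay, the tolerance grid swept when locating the
#' sensitivity plateau, and the plateau slack.
#'
#' @param max_tolerance Maximum acceptable delay delta_T in seconds,
#'   bounded by hardware hysteresis and human reaction speed.
#' @param delta_grid Increasing grid of tolerances (seconds) over which
#'   the sensitivity curve is evaluated.
#' @param plateau_epsilon Sensitivity slack (percentage points) below the
#'   plateau level still counted as "on the plateau". 0 demands a strict
#'   plateau.
#' @return An object of class \code{"validation_config"}.
#' @export
validation_config <- function(max_tolerance = 5, delta_grid = 1:10,
                              plateau_epsilon = 0) {
  if (is.unsorted(delta_grid, strictly = TRUE))
    stop("`delta_grid` must be strictly increasing", call. = FALSE)
  if (max_tolerance < min(delta_grid) || max_tolerance > max(delta_grid))
    stop("`max_tolerance` must lie within the span of `delta_grid`",
         call. = FALSE)
  if (plateau_epsilon < 0)
    stop("`plateau_epsilon` must be >= 0", call. = FALSE)
  structure(list(max_tolerance = max_tolerance, delta_grid = delta_grid,
                 plateau_epsilon = plateau_epsilon),
            class = "validation_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys: \code{window}, \code{range_min_mm}, \code{range_max_mm},
#' \code{sensor_max_mm}, \code{sample_period_s} (classifier);
#' \code{min_bout_s}, \code{filtered_states} (clinical filter);
#' \code{max_tolerance_s}, \code{delta_grid_s}, \code{plateau_epsilon}
#' (validation). Missing keys fall back to the defaults, which are the
#' published operating point (omega = 8, 300--2000 mm gate, 8191 mm
#' saturation, 60 s filter, delta_T = 5 s over a 1--10 s grid).
#'
#' @param path Path to a YAML file, or \code{NULL} for pure defaults.
#' @return A list with elements \code{classifier}, \code{filter} and
#'   \code{validation}.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  pick <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  list(
    classifier = ddc_config(
      window = pick("window", 8),
      range_min = pick("range_min_mm", 300),
      range_max = pick("range_max_mm", 2000),
      sensor_max = pick("sensor_max_mm", 8191),
      sample_period = pick("sample_period_s", 0.3)
    ),
    filter = clinical_filter_config(
      min_bout = pick("min_bout_s", 60),
      filtered_states = pick("filtered_states", c("stand", "away"))
    ),
    validation = validation_config(
      max_tolerance = pick("max_tolerance_s", 5),
      delta_grid = pick("delta_grid_s", 1:10),
      plateau_epsilon = pick("plateau_epsilon", 0)
    )
  )
}

#' Admissible posture states
#'
#' @return The character vector \code{c("sit", "stand", "away")}.
#' @export
posture_states <- function() c("sit", "stand", "away")
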