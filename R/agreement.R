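#' Bland-Altman agreement between sensor and ground-truth durations
#'
#' Classic Bland-Altman analysis of paired duration measurements, in
#' minutes: differences d = sensor - truth, mean bias = mean(d), 95%
#' limits of agreement = bias +/- 1.96 * SD(d) (sample SD, n - 1
#' denominator). Proportional bias is probed by ordinary least squares
#' of the differences on the pair means; the slope's two-sided t-test
#' p-value is reported (undefined below n = 3 or when the regression is
#' degenerate, e.g. constant differences or constant means).
#'
#' @param sensor_durations,truth_durations Equal-length paired duration
#'   vectors in minutes (one entry per matched event).
#' @return An object of class \code{"bland_altman"}: list with
#'   \code{mean_bias}, \code{loa_half_width}, \code{loa_lower},
#'   \code{loa_upper} (min), \code{slope}, \code{slope_p}, \code{n},
#'   and \code{data} (means and differences, for plotting).
#' @export
bland_altman <- function(sensor_durations, truth_durations) {
  if (length(sensor_durations) != length(truth_durations))
    stop("paired sequences must have equal length", call. = FALSE)
  n <- length(sensor_durations)
  if (n < 2L)
    stop("Bland-Altman agreement undefined for n < 2", call. = FALSE)
  d <- sensor_durations - truth_durations
  m <- (sensor_durations + truth_durations) / 2
  bias <- mean(d)
  half <- 1.96 * stats::sd(d)
  slope <- 0
  slope_p <- NA_real_
  if (stats::var(m) > 0 && stats::var(d) > 0) {
    fit <- stats::lm(d ~ m)
    slope <- unname(stats::coef(fit)[2])
    if (n >= 3L) {
      sm <- summary(fit)$coefficients
      if (nrow(sm) == 2L && !is.nan(sm[2, 4])) slope_p <- sm[2, 4]
    }
  }
  structure(
    list(mean_bias = bias, loa_half_width = half,
         loa_lower = bias - half, loa_upper = bias + half,
         slope = slope, slope_p = slope_p, n = n,
         data = data.frame(mean = m, difference = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (minutes)\n")
  cat(sprintf("  n pairs    : %d\n", x$n))
  cat(sprintf("  mean bias  : %.3f min\n", x$mean_bias))
  cat(sprintf("  95%% LoA    : [%.3f, %.3f] (half-width %.3f)\n",
              x$loa_lower, x$loa_upper, x$loa_half_width))
  if (is.na(x$slope_p))
    cat(sprintf("  prop. bias : slope %.4f (p undefined)\n", x$slope))
  else
    cat(sprintf("  prop. bias : slope %.4f (p = %.3f)\n",
                x$slope, x$slope_p))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$data$mean, x$data$difference,
       xlab = "mean of sensor and truth (min)",
       ylab = "sensor - truth (min)", ...)
  graphics::abline(h = c(x$mean_bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2))
  invisible(x)
}
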