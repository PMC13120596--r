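#' Participant geometry profile
#'
#' Maps a participant's height to the per-state target distances the two
#' sensors would read. The seated torso distance grows with height --
#' taller users sit further from a screen-mounted sensor -- and is
#' interpolated linearly from 600 mm at 160 cm to 900 mm at 190 cm. The
#' standing torso and head distances sit mid-gate (the exact value is
#' immaterial to the classifier, which only tests gate membership), and
#' the head channel saturates at the sensor maximum while seated, since
#' the upward sensor aims just above seated head height.
#'
#' @param height Participant height in cm, within [160, 190].
#' @param config A \code{\link{ddc_config}} (supplies the gate and the
#'   saturation code).
#' @return An object of class \code{"participant_profile"}: list with
#'   \code{height}, \code{seated_torso_mm}, \code{standing_torso_mm},
#'   \code{standing_head_mm}, \code{seated_head_mm}.
#' @export
participant_profile <- function(height, config = ddc_config()) {
  if (height < 160 || height > 190)
    stop("`height` must be within [160, 190] cm", call. = FALSE)
  mid_gate <- (config$range_min + config$range_max) / 2
  prof <- list(
    height = height,
    seated_torso_mm = 600 + (height - 160) / 30 * 300,
    standing_torso_mm = mid_gate,
    standing_head_mm = mid_gate,
    seated_head_mm = config$sensor_max
  )
  in_gate <- function(d) d >= config$range_min && d <= config$range_max
  if (!in_gate(prof$seated_torso_mm) || !in_gate(prof$standing_torso_mm) ||
      !in_gate(prof$standing_head_mm))
    stop("profile distances fall outside the detection gate", call. = FALSE)
  class(prof) <- "participant_profile"
  prof
}

#' Sensor noise and artifact model
#'
#' Controls how faithfully a synthesised stream mimics a real desk
#' deployment: Gaussian ranging noise on in-detection samples, sporadic
#' single-sample dropout spikes to the saturation code, postural-sway
#' excursions (brief out-of-range artifacts while standing, the
#' mechanism that fragments standing bouts), the chair-effect occlusion
#' (the chair back mimicking a seated torso while the user is away),
#' and the finite speed of real postural transitions.
#'
#' @param gaussian_sd SD of ranging noise in mm, applied to samples whose
#'   target is below saturation.
#' @param dropout_prob Per-sample, per-channel probability of a spike to
#'   the sensor maximum.
#' @param sway_rate Expected number of sway artifacts per minute of
#'   standing; each artifact drives both channels out of range for 0.5
#'   to 2 s.
#' @param chair_effect If \code{TRUE}, the torso channel keeps reading a
#'   seated-torso distance during away bouts (static chair-back
#'   reflection).
#' @param transition_ramp Seconds a postural transition takes; distances
#'   ramp linearly between the old and new targets.
#' @param seed Optional integer; when given, stream synthesis is
#'   reproducible bit-for-bit.
#' @return An object of class \code{"noise_model"}.
#' @export
noise_model <- function(gaussian_sd = 15, dropout_prob = 0.005,
                        sway_rate = 0, chair_effect = FALSE,
                        transition_ramp = 0.3, seed = NULL) {
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("`dropout_prob` must be in [0, 1]", call. = FALSE)
  if (gaussian_sd < 0 || sway_rate < 0 || transition_ramp < 0)
    stop("noise magnitudes must be >= 0", call. = FALSE)
  structure(list(gaussian_sd = gaussian_sd, dropout_prob = dropout_prob,
                 sway_rate = sway_rate, chair_effect = chair_effect,
                 transition_ramp = transition_ramp, seed = seed),
            class = "noise_model")
}

#' An artifact-free noise model
#'
#' Convenience constructor: no ranging noise, no dropouts, no sway, no
#' chair effect. Postural transitions still take \code{transition_ramp}
#' seconds -- movement is behaviour, not noise -- so classifier latency
#' remains observable.
#'
#' @inheritParams noise_model
#' @return A \code{\link{noise_model}}.
#' @export
noise_free <- function(transition_ramp = 0.3, seed = NULL) {
  noise_model(gaussian_sd = 0, dropout_prob = 0, sway_rate = 0,
              chair_effect = FALSE, transition_ramp = transition_ramp,
              seed = seed)
}

#' Generate a scripted behaviour protocol
#'
#' Builds the ground-truth schedule a participant follows. Three
#' protocols are supported: \code{"P1"}, static postural monitoring
#' (default 8 sit + 9 stand bouts, durations uniform on 60--150 s);
#' \code{"P2"}, presence versus absence (default 2 sit + 6 stand + 9
#' away bouts, same duration range); \code{"P3"}, the desk-squat
#' gesture (10 cycles at 6 s per cycle, rendered as 20 alternating 3-s
#' half-bouts starting from the seated baseline). Consecutive bouts
#' always differ in state.
#'
#' @param protocol_id \code{"P1"}, \code{"P2"} or \code{"P3"}.
#' @param participant_id Label for the simulated participant.
#' @param bout_counts Named vector of bouts per state overriding the
#'   protocol default (ignored for P3).
#' @param duration_range Two-element numeric, bout duration bounds in
#'   seconds for P1/P2.
#' @param cycles Number of squat cycles for P3.
#' @param seed Optional integer; the same seed yields the identical
#'   script.
#' @return An object of class \code{"protocol_script"}: list with
#'   \code{protocol_id}, \code{participant_id} and \code{actions}
#'   (data frame \code{state}, \code{duration_s}).
#' @export
generate_script <- function(protocol_id = c("P1", "P2", "P3"),
                            participant_id = "U1", bout_counts = NULL,
                            duration_range = c(60, 150), cycles = 10,
                            seed = NULL) {
  protocol_id <- match.arg(protocol_id)
  if (!is.null(seed)) set.seed(seed)
  if (protocol_id == "P3") {
    if (cycles < 1) stop("`cycles` must be >= 1", call. = FALSE)
    states <- rep(c("stand", "sit"), cycles)
    durations <- rep(3, 2 * cycles)
  } else {
    counts <- if (!is.null(bout_counts)) bout_counts
              else if (protocol_id == "P1") c(sit = 8, stand = 9)
              else c(sit = 2, stand = 6, away = 9)
    if (any(counts <= 0) || is.null(names(counts)))
      stop("`bout_counts` must be positive named counts", call. = FALSE)
    states <- interleave_states(counts)
    durations <- round(stats::runif(length(states),
                                    duration_range[1], duration_range[2]),
                       3)
  }
  structure(
    list(protocol_id = protocol_id, participant_id = participant_id,
         actions = data.frame(state = states, duration_s = durations)),
    class = "protocol_script"
  )
}

# Arrange state counts into a sequence with no two equal neighbours,
# always spending the most frequent remaining state first.
interleave_states <- function(counts) {
  remaining <- counts
  out <- character(sum(counts))
  prev <- ""
  for (i in seq_along(out)) {
    cand <- remaining[names(remaining) != prev & remaining > 0]
    if (length(cand) == 0L)
      stop("bout counts cannot be arranged without adjacent repeats",
           call. = FALSE)
    pick <- names(cand)[which.max(cand)]
    out[i] <- pick
    remaining[pick] <- remaining[pick] - 1
    prev <- pick
  }
  out
}

#' @export
print.protocol_script <- function(x, ...) {
  cat(sprintf("Protocol %s script for %s: %d bouts, %.0f s total\n",
              x$protocol_id, x$participant_id, nrow(x$actions),
              sum(x$actions$duration_s)))
  print(table(x$actions$state))
  invisible(x)
}

#' Render a protocol script into a sensor stream with ground truth
#'
#' Samples the two distance channels at the configured rate for the full
#' scripted duration. Each state maps to target distances from the
#' participant profile; at every scripted change the targets ramp
#' linearly over \code{transition_ramp} seconds. Noise and artifacts are
#' then injected per the \code{\link{noise_model}}. The ground-truth
#' transition log carries one event per scripted bout, at the exact
#' scripted change times.
#'
#' @param script A \code{\link{generate_script}} result.
#' @param profile A \code{\link{participant_profile}}.
#' @param noise A \code{\link{noise_model}}.
#' @param config A \code{\link{ddc_config}}.
#' @param start_ms Epoch offset of the first sample in ms.
#' @return List with \code{stream} (data frame \code{timestamp_ms},
#'   \code{torso_mm}, \code{head_mm}), \code{truth} (event log) and
#'   \code{end_ms} (timestamp closing the final bout).
#' @export
synthesize_stream <- function(script, profile, noise = noise_model(),
                              config = ddc_config(), start_ms = 0) {
  if (!inherits(script, "protocol_script") || nrow(script$actions) == 0L)
    stop("`script` must be a non-empty protocol_script", call. = FALSE)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  actions <- script$actions
  total_s <- sum(actions$duration_s)
  period_ms <- config$sample_period * 1000
  n <- floor(total_s * 1000 / period_ms) + 1L
  t_rel <- (seq_len(n) - 1L) * config$sample_period  # seconds from start

  targets <- function(state) switch(
    state,
    sit = c(profile$seated_torso_mm, profile$seated_head_mm),
    stand = c(profile$standing_torso_mm, profile$standing_head_mm),
    away = c(if (noise$chair_effect) profile$seated_torso_mm
             else config$sensor_max,
             config$sensor_max)
  )
  change_s <- c(0, cumsum(actions$duration_s))  # bout boundaries
  n_bouts <- nrow(actions)
  torso <- numeric(n); head <- numeric(n)
  for (b in seq_len(n_bouts)) {
    tgt <- targets(actions$state[b])
    # the final bout also claims a sample landing exactly on the end time
    idx <- if (b == n_bouts) which(t_rel >= change_s[b])
           else which(t_rel >= change_s[b] & t_rel < change_s[b + 1])
    if (length(idx) == 0L) next
    torso[idx] <- tgt[1]; head[idx] <- tgt[2]
    if (b > 1L && noise$transition_ramp > 0) {
      prev_tgt <- targets(actions$state[b - 1])
      frac <- (t_rel[idx] - change_s[b]) / noise$transition_ramp
      ramp <- idx[frac < 1]
      fr <- frac[frac < 1]
      torso[ramp] <- prev_tgt[1] + fr * (tgt[1] - prev_tgt[1])
      head[ramp] <- prev_tgt[2] + fr * (tgt[2] - prev_tgt[2])
    }
  }

  # Gaussian ranging noise only where the channel actually detects a
  # surface; the saturation code is an exact sentinel, not a measurement.
  if (noise$gaussian_sd > 0) {
    det_t <- torso < config$sensor_max
    det_h <- head < config$sensor_max
    torso[det_t] <- torso[det_t] +
      stats::rnorm(sum(det_t), 0, noise$gaussian_sd)
    head[det_h] <- head[det_h] +
      stats::rnorm(sum(det_h), 0, noise$gaussian_sd)
  }
  if (noise$dropout_prob > 0) {
    torso[stats::runif(n) < noise$dropout_prob] <- config$sensor_max
    head[stats::runif(n) < noise$dropout_prob] <- config$sensor_max
  }
  if (noise$sway_rate > 0) {
    for (b in which(actions$state == "stand")) {
      dur <- actions$duration_s[b]
      k <- stats::rpois(1, noise$sway_rate * dur / 60)
      if (k == 0L) next
      at <- stats::runif(k, change_s[b], change_s[b + 1])
      len <- stats::runif(k, 0.5, 2)
      for (j in seq_len(k)) {
        hit <- t_rel >= at[j] & t_rel < pmin(at[j] + len[j], change_s[b + 1])
        torso[hit] <- config$sensor_max
        head[hit] <- config$sensor_max
      }
    }
  }
  torso <- round(pmin(pmax(torso, 0), config$sensor_max))
  head <- round(pmin(pmax(head, 0), config$sensor_max))

  truth <- data.frame(
    timestamp_ms = start_ms + round(change_s[-length(change_s)] * 1000),
    state = actions$state
  )
  list(
    stream = data.frame(timestamp_ms = start_ms + round(t_rel * 1000),
                        torso_mm = torso, head_mm = head),
    truth = truth,
    end_ms = start_ms + round(total_s * 1000)
  )
}

#' Simulate a multi-participant protocol session
#'
#' Runs \code{\link{generate_script}} and \code{\link{synthesize_stream}}
#' for a panel of participants whose heights span the study range
#' (160--190 cm by default), deriving independent per-participant RNG
#' substreams from one base seed.
#'
#' @inheritParams generate_script
#' @param n_participants Number of participants.
#' @param heights Heights in cm, recycled to \code{n_participants}.
#' @param noise A \code{\link{noise_model}} (its own \code{seed} field is
#'   ignored here; use \code{seed}).
#' @param config A \code{\link{ddc_config}}.
#' @param seed Base integer seed for the whole session.
#' @return A named list (\code{"U1"} ...), each element a list with
#'   \code{script}, \code{profile}, \code{stream}, \code{truth},
#'   \code{end_ms}.
#' @export
simulate_participants <- function(protocol_id, n_participants = 7,
                                  heights = NULL, noise = noise_model(),
                                  config = ddc_config(), seed = 1) {
  if (is.null(heights))
    heights <- seq(160, 190, length.out = n_participants)
  heights <- rep_len(heights, n_participants)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_participants)
  out <- lapply(seq_len(n_participants), function(i) {
    set.seed(sub_seeds[i])
    script <- generate_script(protocol_id,
                              participant_id = paste0("U", i))
    profile <- participant_profile(heights[i], config)
    sim <- synthesize_stream(script, profile, noise, config)
    c(list(script = script, profile = profile), sim)
  })
  names(out) <- paste0("U", seq_len(n_participants))
  out
}
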