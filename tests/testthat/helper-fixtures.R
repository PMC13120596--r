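# Shared fixtures and independent brute-force oracles.

make_stream <- function(torso, head = torso, start_ms = 0, period_ms = 300) {
  data.frame(
    timestamp_ms = start_ms + (seq_along(torso) - 1) * period_ms,
    torso_mm = torso,
    head_mm = head
  )
}

make_events <- function(times_s, states) {
  data.frame(timestamp_ms = times_s * 1000, state = states)
}

# A bare alignment object carrying just what the tolerance statistics
# need, for direct unit tests of sensitivity/delta_min.
fake_alignment <- function(deltas_s, n_truth,
                           n_sensor = length(deltas_s)) {
  structure(
    list(pairs = data.frame(delta_s = deltas_s),
         missed_truth = data.frame(),
         spurious_sensor = data.frame(),
         n_sensor = n_sensor, n_truth = n_truth),
    class = "event_alignment"
  )
}

# O(n * window) windowed-mean oracle, written naively on purpose.
bf_trailing_mean <- function(x, window) {
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - window + 1):i])
  }, numeric(1))
}

# Neighbour-scan oracle for transition extraction.
bf_transitions <- function(states) {
  keep <- 1L
  for (i in seq_along(states$state)[-1]) {
    if (states$state[i] != states$state[i - 1]) keep <- c(keep, i)
  }
  out <- states[keep, c("timestamp_ms", "state")]
  rownames(out) <- NULL
  out
}

# Exhaustive minimum-total-cost matching oracle: enumerates every
# injective assignment of the smaller event set into the larger and
# returns the minimum achievable sum of |dt| (seconds).
bf_min_cost <- function(sensor_ms, truth_ms) {
  ns <- length(sensor_ms); nt <- length(truth_ms)
  if (ns == 0 || nt == 0) return(0)
  small <- if (ns <= nt) sensor_ms else truth_ms
  large <- if (ns <= nt) truth_ms else sensor_ms
  k <- length(small)
  idx_sets <- utils::combn(length(large), k, simplify = FALSE)
  perms <- all_perms(k)
  best <- Inf
  for (set in idx_sets) {
    for (p in perms) {
      cost <- sum(abs(small - large[set[p]])) / 1000
      if (cost < best) best <- cost
    }
  }
  best
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# Realistic random event logs: well-separated truth transitions with
# small sensor latency jitter, plus (mode-dependent) missed or spurious
# events -- the regime a desk sensor actually produces.
random_log_pair <- function(n_truth, gap_range = c(30, 120),
                            jitter_s = 2,
                            mode = c("clean", "miss", "spur")) {
  mode <- match.arg(mode)
  truth_ms <- cumsum(runif(n_truth, gap_range[1], gap_range[2])) * 1000
  sensor_ms <- truth_ms + runif(n_truth, -jitter_s, jitter_s) * 1000
  if (mode == "miss")
    sensor_ms <- sensor_ms[-sample(n_truth, 1)]
  if (mode == "spur")
    sensor_ms <- c(sensor_ms, max(truth_ms) + runif(1, 10, 20) * 1000)
  states <- function(n) sample(c("sit", "stand", "away"), n, replace = TRUE)
  list(
    sensor = data.frame(timestamp_ms = sort(sensor_ms),
                        state = states(length(sensor_ms))),
    truth = data.frame(timestamp_ms = sort(truth_ms),
                       state = states(n_truth))
  )
}

# Random contiguous bout sequence with alternating-state runs.
random_bouts <- function(n, min_s = 5, max_s = 200) {
  states <- character(n)
  states[1] <- sample(c("sit", "stand", "away"), 1)
  for (i in seq_len(n)[-1])
    states[i] <- sample(setdiff(c("sit", "stand", "away"), states[i - 1]), 1)
  dur_ms <- round(runif(n, min_s, max_s) * 1000)
  start <- cumsum(c(0, dur_ms[-n]))
  data.frame(state = states, start_ms = start, end_ms = start + dur_ms,
             duration_s = dur_ms / 1000)
}
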