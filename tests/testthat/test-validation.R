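test_that("greedy nearest-neighbour alignment pairs events and isolates misses", {
  a <- align_events(make_events(10, "sit"), make_events(11.5, "sit"))
  expect_equal(nrow(a$pairs), 1L)
  expect_equal(a$pairs$delta_s, 1.5)

  a2 <- align_events(make_events(c(10, 100), c("sit", "stand")),
                     make_events(c(12, 60, 101),
                                 c("sit", "away", "stand")))
  expect_equal(a2$pairs$sensor_ms, c(10000, 100000))
  expect_equal(a2$pairs$truth_ms, c(12000, 101000))
  expect_equal(a2$missed_truth$timestamp_ms, 60000)
  expect_equal(nrow(a2$spurious_sensor), 0L)

  empty <- make_events(numeric(0), character(0))
  a3 <- align_events(empty, make_events(c(1, 2), c("sit", "stand")))
  expect_equal(nrow(a3$pairs), 0L)
  expect_equal(nrow(a3$missed_truth), 2L)
  a4 <- align_events(make_events(c(1, 2), c("sit", "stand")), empty)
  expect_equal(nrow(a4$spurious_sensor), 2L)
})

test_that("greedy alignment attains the exhaustive minimum-cost matching on realistic logs", {
  set.seed(99)
  for (rep in 1:40) {
    logs <- random_log_pair(sample(2:6, 1),
                            mode = sample(c("clean", "miss", "spur"), 1))
    a <- align_events(logs$sensor, logs$truth)
    expect_equal(nrow(a$pairs),
                 min(nrow(logs$sensor), nrow(logs$truth)))
    expect_equal(sum(a$pairs$delta_s),
                 bf_min_cost(logs$sensor$timestamp_ms,
                             logs$truth$timestamp_ms),
                 tolerance = 1e-9)
  }
})

test_that("ties in |dt| break toward the earlier truth event", {
  a <- align_events(make_events(10, "sit"),
                    make_events(c(9, 11), c("sit", "stand")))
  expect_equal(a$pairs$truth_ms, 9000)
  expect_equal(a$missed_truth$timestamp_ms, 11000)
})

test_that("sensitivity counts matched events within the tolerance", {
  al <- fake_alignment(c(1, 2, 6), n_truth = 4)
  expect_equal(sensitivity_at(al, 3), 50)
  expect_equal(sensitivity_at(al, 10), 75)
  perfect <- fake_alignment(rep(0, 5), n_truth = 5)
  expect_equal(sensitivity_at(perfect, 1), 100)
  expect_error(sensitivity_at(fake_alignment(numeric(0), 0), 3),
               "undefined")
})

test_that("sensitivity is non-decreasing in the tolerance", {
  set.seed(5)
  for (rep in 1:25) {
    al <- fake_alignment(runif(sample(1:20, 1), 0, 12),
                         n_truth = sample(20:30, 1))
    phi <- vapply(0:12, function(d) sensitivity_at(al, d), numeric(1))
    expect_true(all(diff(phi) >= 0))
    expect_true(all(phi >= 0 & phi <= 100))
  }
})

test_that("delta_min is the first grid tolerance on the capped plateau", {
  # 40 / 70 / 81 / 81 ... percent: plateau starts at 3 s
  al <- fake_alignment(c(rep(0.5, 40), rep(1.5, 30), rep(2.5, 11)),
                       n_truth = 100)
  curve <- find_delta_min(al)
  expect_equal(curve$values[1:4], c(40, 70, 81, 81))
  expect_equal(curve$delta_min, 3)

  # saturated from the first grid point
  curve2 <- find_delta_min(fake_alignment(rep(0.2, 10), n_truth = 10))
  expect_equal(curve2$delta_min, 1)

  # still climbing through the whole grid: capped at delta_T
  al3 <- fake_alignment(seq(0.5, 9.5, by = 1), n_truth = 10)
  expect_warning(curve3 <- find_delta_min(al3), "capped")
  expect_equal(curve3$delta_min, 5)
})

test_that("duration errors summarise matched-pair bout differences", {
  sensor_ev <- make_events(c(0, 61), c("sit", "stand"))
  truth_ev <- make_events(c(0, 60), c("sit", "stand"))
  es <- duration_errors(bouts_from_events(sensor_ev, 103000),
                        bouts_from_events(truth_ev, 100000),
                        align_events(sensor_ev, truth_ev),
                        delta_min = 5)
  expect_equal(es$mae, 1.5)  # diffs +1 s and +2 s
  expect_equal(es$mean_diff, 1.5 / 60)
  expect_equal(es$ci95_half, 1.96 * sd(c(1, 2)) / sqrt(2) / 60)
  expect_equal(es$count_bias, 0L)
  expect_equal(es$n, 2L)

  # identical logs: zero error, zero bias
  es2 <- duration_errors(bouts_from_events(truth_ev, 100000),
                         bouts_from_events(truth_ev, 100000),
                         align_events(truth_ev, truth_ev), 5)
  expect_equal(es2$mae, 0)
  expect_equal(es2$count_bias, 0L)

  # raw-count bias is sensor minus truth
  sens_log <- make_events(seq(0, by = 100, length.out = 60),
                    rep(c("sit", "stand"), 30))
  truth_log <- make_events(seq(0, by = 100, length.out = 63),
                    rep(c("sit", "stand"), length.out = 63))
  es3 <- duration_errors(bouts_from_events(sens_log, 6300000),
                         bouts_from_events(truth_log, 6300000),
                         align_events(sens_log, truth_log), 5)
  expect_equal(es3$count_bias, -3L)

  expect_error(
    duration_errors(bouts_from_events(sensor_ev, 103000),
                    bouts_from_events(truth_ev, 100000),
                    fake_alignment(numeric(0), 2), 5),
    "undefined")
})

test_that("every pair used for the MAE lies within delta_min", {
  set.seed(13)
  logs <- random_log_pair(8, jitter_s = 4)
  al <- align_events(logs$sensor, logs$truth)
  end_ms <- max(logs$sensor$timestamp_ms, logs$truth$timestamp_ms) + 10000
  dm <- 2
  es <- duration_errors(bouts_from_events(logs$sensor, end_ms),
                        bouts_from_events(logs$truth, end_ms), al, dm)
  expect_equal(es$n, sum(al$pairs$delta_s <= dm))
})

test_that("a missed event lengthens the preceding sensor bout by the missed bout's duration", {
  truth_ev <- make_events(c(0, 100, 170, 300),
                          c("sit", "stand", "away", "sit"))
  sensor_ev <- truth_ev[-3, ]  # the away transition is missed
  tb <- bouts_from_events(truth_ev, 400000)
  sb <- bouts_from_events(sensor_ev, 400000)
  # sensor stand bout runs to the next detected event: 100 -> 300 s
  expect_equal(sb$duration_s[sb$state == "stand"], 200)
  expect_equal(sb$duration_s[2] - tb$duration_s[2],
               tb$duration_s[tb$state == "away"])
  al <- align_events(sensor_ev, truth_ev)
  expect_equal(al$missed_truth$state, "away")
  es <- duration_errors(sb, tb, al, 5)
  expect_equal(es$count_bias, -1L)
})

test_that("per-user MAE stratifies and pools by event weight", {
  mk <- function(diff_s) {
    s <- make_events(c(0, 100 + diff_s), c("sit", "stand"))
    g <- make_events(c(0, 100), c("sit", "stand"))
    list(sensor_bouts = bouts_from_events(s, 300000),
         truth_bouts = bouts_from_events(g, 300000),
         alignment = align_events(s, g))
  }
  res <- per_user_mae(list(A = mk(0), B = mk(2)), delta_min = 5)
  # each user's two events: diffs {0, 0} and {+2, -2} s
  expect_equal(res$mae_u, c(0, 2))
  expect_equal(attr(res, "pooled_mae"), 1)

  one <- per_user_mae(list(A = mk(1)), delta_min = 5)
  ref <- duration_errors(mk(1)$sensor_bouts, mk(1)$truth_bouts,
                         mk(1)$alignment, 5)
  expect_equal(one$mae_u, ref$mae)

  # a user with no matches inside delta_min is flagged, not dropped
  far_s <- make_events(c(20, 120), c("sit", "stand"))
  far_g <- make_events(c(0, 100), c("sit", "stand"))
  far <- list(sensor_bouts = bouts_from_events(far_s, 300000),
              truth_bouts = bouts_from_events(far_g, 300000),
              alignment = align_events(far_s, far_g))
  res2 <- per_user_mae(list(A = mk(0), B = far), delta_min = 5)
  expect_true(res2$undefined[res2$user_id == "B"])
  expect_true(is.na(res2$mae_u[res2$user_id == "B"]))
})
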