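# Build an alignment whose matched pairs carry prescribed truth/sensor
# label combinations, events spaced well apart.
labelled_alignment <- function(truth_states, sensor_states) {
  stopifnot(length(truth_states) == length(sensor_states))
  t_ms <- seq_along(truth_states) * 100000
  structure(
    list(pairs = data.frame(sensor_ms = t_ms + 500, truth_ms = t_ms,
                            sensor_state = sensor_states,
                            truth_state = truth_states,
                            delta_s = 0.5),
         missed_truth = data.frame(timestamp_ms = numeric(0),
                                   state = character(0)),
         spurious_sensor = data.frame(timestamp_ms = numeric(0),
                                      state = character(0)),
         n_sensor = length(truth_states),
         n_truth = length(truth_states)),
    class = "event_alignment"
  )
}

# The sit/stand/away mislabelling pattern of a presence protocol with
# 14 sit, 42 stand and 63 away scripted events.
p2_style_alignment <- function() {
  truth <- c(rep("sit", 14), rep("stand", 42), rep("away", 63))
  sensor <- c(rep("sit", 13), "away",                 # 1 sit -> away
              rep("stand", 40), "sit", "away",        # 42 stand
              rep("away", 61), "sit", "sit")          # 63 away
  labelled_alignment(truth, sensor)
}

test_that("the confusion table accounts for every ground-truth event", {
  # all-correct two-state session: clean diagonal
  cm <- build_confusion(labelled_alignment(
    c(rep("sit", 56), rep("stand", 63)),
    c(rep("sit", 56), rep("stand", 63))))
  expect_equal(unname(diag(cm$table)), c(56, 63, 0))
  expect_equal(sum(cm$table) - sum(diag(cm$table)), 0)

  cm2 <- build_confusion(p2_style_alignment())
  expect_equal(unname(rowSums(cm2$table)), c(14, 42, 63))
  expect_equal(sum(cm2$table), 119)
  sit <- cm2$per_class[cm2$per_class$state == "sit", ]
  expect_equal(sit$tp, 13)
  expect_equal(sit$fp, 3)
  expect_equal(sit$fn, 1)
  expect_equal(sit$tn, 102)

  empty <- align_events(make_events(numeric(0), character(0)),
                        make_events(numeric(0), character(0)))
  expect_true(all(build_confusion(empty)$table == 0))
})

test_that("a missed truth event is attributed to the sensor's prevailing state", {
  # sensor never saw the user return to sit at t = 200 s and stayed away
  sensor <- make_events(c(0, 100), c("sit", "away"))
  truth <- make_events(c(0, 100, 200), c("sit", "away", "sit"))
  cm <- build_confusion(align_events(sensor, truth))
  expect_equal(cm$table["sit", "away"], 1)
  expect_equal(sum(cm$table), 3)
})

test_that("one-vs-rest metrics reproduce the worked percentages", {
  cm <- build_confusion(p2_style_alignment())
  sit <- class_metrics(cm, "sit")
  expect_equal(round(sit$precision, 2), 81.25)
  expect_equal(round(sit$recall, 2), 92.86)
  expect_equal(round(sit$specificity, 2), 97.14)
  expect_equal(round(sit$f1, 2), 86.67)
  stand <- class_metrics(cm, "stand")
  expect_equal(round(stand$recall, 2), 95.24)
  expect_equal(round(stand$precision, 2), 100)
  away <- class_metrics(cm, "away")
  expect_equal(round(away$f1, 2), 96.83)

  # perfect classification: every metric 100 and F1 is the identity
  perfect <- build_confusion(labelled_alignment(
    rep(posture_states(), 10), rep(posture_states(), 10)))
  for (s in posture_states()) {
    m <- class_metrics(perfect, s)
    expect_equal(c(m$precision, m$recall, m$specificity, m$f1),
                 rep(100, 4))
  }
})

test_that("metric identities hold on random confusion tables", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    al <- labelled_alignment(sample(posture_states(), n, replace = TRUE),
                             sample(posture_states(), n, replace = TRUE))
    cm <- build_confusion(al)
    expect_equal(sum(cm$table), n)
    for (s in posture_states()) {
      row <- cm$per_class[cm$per_class$state == s, ]
      expect_equal(row$tp + row$fn, sum(cm$table[s, ]))
      expect_equal(row$tp + row$fp, sum(cm$table[, s]))
      expect_equal(row$tp + row$fp + row$fn + row$tn, n)
      m <- class_metrics(cm, s)
      if (!is.nan(m$f1)) {
        expect_gte(m$f1, min(m$precision, m$recall) - 1e-9)
        expect_lte(m$f1, max(m$precision, m$recall) + 1e-9)
        expect_equal(m$f1, 2 * m$precision * m$recall /
                             (m$precision + m$recall))
      }
    }
  }
})

test_that("zero denominators are flagged undefined, not reported as zero", {
  # no event was ever labelled stand by either side except truth misses
  cm <- build_confusion(labelled_alignment(rep("sit", 4), rep("sit", 4)))
  m <- class_metrics(cm, "stand")
  expect_true(is.nan(m$precision))
  expect_true(is.nan(m$recall))
  expect_true(all(c("precision", "recall", "f1") %in% m$undefined))
  expect_false("specificity" %in% m$undefined)
})
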