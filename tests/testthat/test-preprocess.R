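test_that("a fully confident trace yields no blink intervals", {
  rec <- flat_recording(5)
  expect_equal(nrow(detect_blinks(rec)), 0L)
})

test_that("a low-confidence run becomes one padded interval", {
  conf <- rep(1, 300)
  conf[100:109] <- 0   # 10 samples starting at t = 99/60
  rec <- flat_recording(5, confidence = conf)
  iv <- detect_blinks(rec)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$reason, "low_confidence")
  expect_equal(iv$start, 99 * dt_60 - 0.033, tolerance = 1e-9)
  expect_equal(iv$end, 108 * dt_60 + 0.033, tolerance = 1e-9)
})

test_that("runs separated by less than the merge gap become one interval", {
  conf <- rep(1, 300)
  conf[100:104] <- 0
  conf[107:111] <- 0   # separated by 2 samples ~ 33 ms < 50 ms
  rec <- flat_recording(5, confidence = conf)
  iv <- detect_blinks(rec)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, 99 * dt_60 - 0.033, tolerance = 1e-9)
  expect_equal(iv$end, 110 * dt_60 + 0.033, tolerance = 1e-9)
})

test_that("clock-gap samples are detected with their own reason", {
  rec <- flat_recording(5)
  rec$gap_flag[150:155] <- TRUE
  iv <- detect_blinks(rec)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$reason, "clock_gap")
})

test_that("interpolation with no intervals is the identity", {
  rec <- flat_recording(5, noise_sd = 0.01, seed = 11)
  out <- interpolate_blinks(rec, detect_blinks(rec))
  expect_identical(out$diameter, rec$diameter)
})

test_that("a dip in a flat trace is restored to the flat level", {
  rec <- flat_recording(5, level = 3)
  rec$diameter[120:130] <- 2.0
  iv <- data.frame(start = 119 * dt_60, end = 131 * dt_60,
                   reason = "low_confidence")
  out <- interpolate_blinks(rec, iv)
  expect_equal(out$diameter, rep(3, length(rec$time)), tolerance = 1e-9)
})

test_that("a dip on a linear ramp is restored onto the ramp line", {
  tm <- grid60(5)
  ramp <- 3 + 0.1 * tm
  rec <- pupil_recording(tm, ramp, rate_hz = rate_60)
  rec$diameter[120:130] <- 2.0
  iv <- data.frame(start = 119 * dt_60, end = 131 * dt_60,
                   reason = "low_confidence")
  out <- interpolate_blinks(rec, iv)
  expect_equal(out$diameter, ramp, tolerance = 1e-6)
})

test_that("interpolation never alters samples outside the padded intervals", {
  rec <- flat_recording(6, noise_sd = 0.05, seed = 12)
  rec$diameter[200:215] <- 1.5
  iv <- data.frame(start = 199 * dt_60, end = 216 * dt_60,
                   reason = "low_confidence")
  out <- interpolate_blinks(rec, iv)
  outside <- rec$time < iv$start | rec$time > iv$end
  expect_identical(out$diameter[outside], rec$diameter[outside])
})

test_that("an interval at the recording edge is filled by a value hold", {
  rec <- flat_recording(5, level = 3, noise_sd = 0.01, seed = 13)
  rec$diameter[1:10] <- 1.2
  iv <- data.frame(start = 0, end = 9 * dt_60, reason = "low_confidence")
  out <- interpolate_blinks(rec, iv)
  inside <- rec$time <= iv$end
  first_valid <- which(!inside)[1]
  expect_equal(out$diameter[inside],
               rep(rec$diameter[first_valid], sum(inside)))
  expect_equal(attr(out, "log")$n_edge_holds, 1L)
})

test_that("hampel filter leaves a constant series unchanged", {
  expect_identical(hampel_filter(rep(2.5, 50)), rep(2.5, 50))
})

test_that("hampel replaces any deviation when the window MAD is zero", {
  # window median = 1, MAD = 0: the spike is replaced by the median
  expect_equal(hampel_filter(c(1, 1, 9, 1, 1)), rep(1, 5))
})

test_that("hampel leaves a slow sinusoid untouched (oracle recheck)", {
  tm <- grid60(4)
  x <- 3 + 0.5 * sin(2 * pi * 0.25 * tm)
  # oracle: recompute the flag per interior sample independently
  flagged <- vapply(3:(length(x) - 2), function(i) {
    w <- x[(i - 2):(i + 2)]
    med <- median(w); mad <- median(abs(w - med))
    dev <- abs(x[i] - med)
    (mad == 0 && dev > 0) || dev > 3 * 1.4826 * mad
  }, logical(1))
  expect_false(any(flagged))
  expect_identical(hampel_filter(x), x)
})

test_that("hampel agrees with an independent implementation away from edges", {
  set.seed(14)
  x <- cumsum(rnorm(200, 0, 0.05)) + 4
  x[c(50, 120)] <- x[c(50, 120)] + 3   # gross spikes
  mine <- hampel_filter(x)
  ref <- pracma::hampel(x, k = 2, t0 = 3)$y
  inner <- 3:198
  expect_equal(mine[inner], ref[inner], tolerance = 1e-12)
})

test_that("hampel is idempotent on smooth series with isolated spikes", {
  # the filter's design domain: a smooth pupil trace plus isolated
  # artifacts (on dense white noise a scaled-MAD rule keeps re-flagging)
  set.seed(15)
  for (rep in 1:5) {
    x <- rep(runif(1, 3, 6), 120)
    at <- seq(10, 110, by = 23) + sample(0:5, 5, replace = TRUE)
    x[at] <- x[at] + runif(5, -3, 3)
    once <- hampel_filter(x)
    expect_identical(hampel_filter(once), once)
    expect_identical(once, rep(x[1], 120))   # artifacts fully repaired
  }
})

trial_events_fixture <- function() {
  toy_events(data.frame(
    trial_id = rep(1:3, each = 3),
    event = rep(c("memory_array", "search_array", "response"), 3),
    onset_s = c(1.0, 2.0, 3.0, 5.0, 6.0, 7.0, 9.0, 10.0, 11.0),
    conditions = "vwm_load=low",
    correct = rep(c(NA, NA, TRUE), 3),
    rt_s = rep(c(NA, NA, 0.5), 3)))
}

test_that("central fixation with no blinks keeps every trial", {
  rec <- flat_recording(13)
  ev <- trial_events_fixture()
  keep <- exclude_trials(rec, ev, detect_blinks(rec))
  expect_true(all(keep$keep))
  expect_true(all(keep$reason == ""))
})

test_that("one eccentric gaze sample during the trial window excludes it", {
  rec <- flat_recording(13)
  rec$gaze_x[rec$time >= 6.4 & rec$time < 6.42] <- 3.0  # trial 2 window
  keep <- exclude_trials(rec, trial_events_fixture(),
                         detect_blinks(rec))
  expect_equal(keep$keep, c(TRUE, FALSE, TRUE))
  expect_equal(keep$reason[2], "gaze")
  # eccentricity uses both axes
  rec2 <- flat_recording(13)
  rec2$gaze_x[400] <- 2.1; rec2$gaze_y[400] <- 2.1  # sqrt(2)*2.1 > 2.8
  keep2 <- exclude_trials(rec2, trial_events_fixture(),
                          detect_blinks(rec2))
  expect_false(all(keep2$keep))
})

test_that("a blink ending 120 ms before a stimulus onset excludes the trial", {
  rec <- flat_recording(13)
  # stimulus onset at 5.0 s; blink [4.6, 4.88] intersects [4.85, 5.15]
  blinks <- data.frame(start = 4.6, end = 4.88, reason = "low_confidence")
  keep <- exclude_trials(rec, trial_events_fixture(), blinks)
  expect_equal(keep$keep, c(TRUE, FALSE, TRUE))
  expect_equal(keep$reason[2], "blink")
  # a blink just outside the 300-ms window does not exclude
  blinks2 <- data.frame(start = 4.6, end = 4.84, reason = "low_confidence")
  keep2 <- exclude_trials(rec, trial_events_fixture(), blinks2)
  expect_true(keep2$keep[2])
})

test_that("trials without a response event are excluded as no_response", {
  rec <- flat_recording(13)
  ev <- toy_events(data.frame(
    trial_id = c(1, 1, 2),
    event = c("memory_array", "response", "memory_array"),
    onset_s = c(1, 2, 5), conditions = "", correct = NA, rt_s = NA))
  keep <- exclude_trials(rec, ev, detect_blinks(rec))
  expect_equal(keep$keep, c(TRUE, FALSE))
  expect_equal(keep$reason[2], "no_response")
})

test_that("shrinking the gaze limit never keeps a trial a larger limit dropped", {
  set.seed(16)
  rec <- flat_recording(13)
  rec$gaze_x <- rnorm(length(rec$time), 0, 1.5)
  ev <- trial_events_fixture()
  blinks <- detect_blinks(rec)
  limits <- c(4, 2.8, 2, 1, 0.5)
  kept <- lapply(limits, function(L)
    exclude_trials(rec, ev, blinks, gaze_limit_deg = L)$keep)
  for (k in seq_along(limits)[-1])
    expect_true(all(kept[[k]] <= kept[[k - 1]]))
})

test_that("epochs from a constant recording are identically zero", {
  rec <- flat_recording(13, level = 3)
  es <- epoch_and_baseline(rec, trial_events_fixture(), "memory_array",
                           epoch_len_s = 2)
  expect_equal(nrow(es$data), 3L)
  expect_equal(max(abs(es$data)), 0)
})

test_that("a 6.5-s epoch at 60 Hz has 390 samples", {
  rec <- flat_recording(40)
  ev <- toy_events(data.frame(
    trial_id = 1, event = c("memory_array", "response"),
    onset_s = c(2, 4), conditions = "", correct = c(NA, TRUE),
    rt_s = c(NA, 0.4)))
  es <- epoch_and_baseline(rec, ev, "memory_array", epoch_len_s = 6.5)
  expect_equal(ncol(es$data), 390L)
})

test_that("a step at onset leaves baseline at zero and the step visible", {
  tm <- grid60(13)
  d <- 3 + 0.4 * (tm >= 5.0)
  rec <- pupil_recording(tm, d, rate_hz = rate_60)
  ev <- trial_events_fixture()   # trial 2's memory array sits on the step
  es <- epoch_and_baseline(rec, ev, "memory_array", epoch_len_s = 1)
  row2 <- which(es$meta$trial_id == 2)
  expect_equal(mean(es$data[row2, ]), 0.4, tolerance = 1e-9)
  row1 <- which(es$meta$trial_id == 1)
  expect_equal(mean(es$data[row1, ]), 0, tolerance = 1e-9)
})

test_that("zero surviving trials give an empty epoch set, not an error", {
  rec <- flat_recording(13)
  ev <- trial_events_fixture()
  keep <- data.frame(trial_id = 1:3, keep = FALSE, reason = "gaze")
  es <- epoch_and_baseline(rec, ev, "memory_array", epoch_len_s = 2,
                           keep = keep)
  expect_s3_class(es, "epoch_set")
  expect_equal(nrow(es$data), 0L)
})

test_that("epochs truncated at the recording end are dropped and logged", {
  rec <- flat_recording(13)   # trial 3 locks at 9 s; 6.5-s epoch overruns
  es <- epoch_and_baseline(rec, trial_events_fixture(), "memory_array",
                           epoch_len_s = 6.5)
  expect_equal(nrow(es$data), 2L)
  expect_equal(attr(es, "log")$n_dropped_truncated, 1L)
})
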