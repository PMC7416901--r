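test_that("the baseline never exceeds a flat trace's level", {
  rec <- flat_recording(10, level = 3)
  b <- choose_baseline(rec, deconv_config())
  expect_lte(b, 3)
  expect_equal(as.numeric(b), 3, tolerance = 1e-9)
})

test_that("a fixed baseline below the trace is accepted as given", {
  rec <- flat_recording(10, level = 2.8, noise_sd = 0.005, seed = 20)
  cfg <- deconv_config(baseline_mode = "fixed", baseline_value = 2.5)
  expect_equal(choose_baseline(rec, cfg), 2.5)
})

test_that("percentile baseline equals an independent smooth-then-clamp oracle", {
  rec <- flat_recording(30, signal = 0.3 * impulse_response(grid60(30) - 5),
                        noise_sd = 0.01, seed = 21)
  cfg <- deconv_config()
  b <- choose_baseline(rec, cfg)
  # oracle: moving average via stats::filter with shrunken edges, then
  # percentile, then clamp at the smoothed minimum
  k <- round(cfg$baseline_smooth_s * rate_60)
  half <- k %/% 2
  sm <- vapply(seq_along(rec$diameter), function(i) {
    mean(rec$diameter[max(1, i - half):min(length(rec$diameter), i + half)])
  }, numeric(1))
  expect_equal(as.numeric(b),
               min(quantile(sm, cfg$baseline_percentile, names = FALSE),
                   min(sm)),
               tolerance = 1e-12)
})

test_that("no pulses are inserted while the observation matches the model", {
  tm <- grid60(5)
  st <- deconv_init(tm, deconv_config(), baseline = 3, reference = 3)
  for (i in seq_along(tm)) st <- deconv_step(st, 3)
  expect_equal(nrow(st$insert_log), 0L)
  expect_equal(nrow(st$pulses), 0L)
  expect_equal(st$residuals, rep(0, length(tm)))
})

test_that("a threshold crossing inserts a pulse back-projected by 500 ms", {
  tm <- grid60(15)
  cfg <- deconv_config()
  st <- deconv_init(tm, cfg, baseline = 4, reference = 4)
  z <- rep(4, length(tm))
  i0 <- which.min(abs(tm - 10))  # first super-threshold frame at t = 10 s
  z[i0:length(z)] <- 4.3
  for (i in seq_along(tm)) st <- deconv_step(st, z[i])
  expect_gt(nrow(st$insert_log), 0L)
  expect_equal(st$insert_log$t_detect[1], tm[i0])
  expect_equal(st$insert_log$onset_s[1], tm[i0] - 0.5)
  expect_equal(st$insert_log$onset_s[1], 9.5, tolerance = 1e-6)
})

test_that("insertions stay separated by the refractory period", {
  tm <- grid60(10)
  cfg <- deconv_config()
  st <- deconv_init(tm, cfg, baseline = 4, reference = 4)
  z <- rep(4, length(tm))
  z[tm >= 3] <- 4.5             # residual stays super-threshold for long
  for (i in seq_along(tm)) st <- deconv_step(st, z[i])
  expect_gt(nrow(st$insert_log), 1L)
  gaps <- diff(st$insert_log$t_detect)
  expect_true(all(gaps >= cfg$refractory_s - 1e-9))
})

test_that("feeding past the end of the grid is an error", {
  tm <- grid60(1)
  st <- deconv_init(tm, deconv_config(), baseline = 3, reference = 3)
  for (i in seq_along(tm)) st <- deconv_step(st, 3)
  expect_error(deconv_step(st, 3), "stream ended")
})

test_that("a single noiseless pulse is recovered at the closed-form scale", {
  tm <- grid60(10)
  p <- tepr_params()
  z <- 4 + 0.35 * impulse_response(tm - 3, p)
  st <- deconv_init(tm, deconv_config(), baseline = 4, reference = 4, p)
  for (i in seq_along(tm)) st <- deconv_step(st, z[i])
  # closed-form single-regressor least squares at the candidate onset
  i_now <- st$insert_log$frame[nrow(st$insert_log)]
  expect_gt(nrow(st$pulses), 0L)
  big <- which.max(st$pulses$scale_mm)
  on <- st$pulses$onset_s[big]
  w0 <- st$time[i_now] - st$config$opt_window_s
  widx <- which(st$time >= w0 & seq_along(tm) <= i_now)
  hk <- impulse_response(st$time[widx] - on, p)
  other <- setdiff(seq_len(nrow(st$pulses)), big)
  target <- z[widx] - 4
  for (k in other)
    target <- target - st$pulses$scale_mm[k] *
      impulse_response(st$time[widx] - st$pulses$onset_s[k], p)
  expect_equal(st$pulses$scale_mm[big], max(0, sum(hk * target) / sum(hk^2)),
               tolerance = 1e-6)
})

test_that("optimising against a flat observation zeroes all free scales", {
  tm <- grid60(6)
  st <- deconv_init(tm, deconv_config(), baseline = 4, reference = 4)
  st$observed <- rep(4, length(tm))
  st$i <- length(tm)
  st$pulses <- data.frame(onset_s = c(3.0, 4.2), scale_mm = c(0.2, 0.1))
  st <- optimize_scales(st)
  # NNLS sits at the boundary: zero scales (zeroed stale candidates are
  # additionally dropped from the active set)
  expect_true(nrow(st$pulses) == 0L || all(st$pulses$scale_mm == 0))
})

test_that("two well-separated pulses fit like two independent single fits", {
  tm <- grid60(10)
  p <- tepr_params()
  z <- 4 + 0.3 * impulse_response(tm - 1, p) +
    0.5 * impulse_response(tm - 8.2, p)
  st <- deconv_init(tm, deconv_config(opt_window_s = 10),
                    baseline = 4, reference = 4, p)
  st$observed <- z
  st$i <- length(tm)
  st$pulses <- data.frame(onset_s = c(1, 8.2), scale_mm = c(0, 0))
  st <- optimize_scales(st)
  # independent per-pulse fits on the full span (orthogonal supports)
  for (k in 1:2) {
    hk <- impulse_response(tm - st$pulses$onset_s[k], p)
    solo <- sum(hk * (z - 4)) / sum(hk^2)
    expect_equal(st$pulses$scale_mm[k], solo, tolerance = 1e-6)
  }
})

test_that("windowed error never increases across an optimisation call", {
  set.seed(22)
  rec <- pulse_recording(c(2, 4.5), c(0.3, 0.4), noise_sd = 0.01,
                         seed = 22)
  cfg <- deconv_config()
  st <- deconv_init(rec$time, cfg, baseline = 4.5,
                    reference = median(rec$diameter))
  z <- rec$diameter
  for (i in seq_along(z)) {
    i_next <- st$i + 1L
    r <- z[i_next] - st$modeled[i_next]
    will_insert <- r > st$threshold &&
      (is.na(st$last_insert) ||
         (i_next - st$last_insert) * st$dt >= cfg$refractory_s - 1e-12)
    if (will_insert) {
      # measure the windowed error before and after the step's refit
      w <- c(max(rec$time[i_next] - cfg$opt_window_s, 0), rec$time[i_next])
      before <- st
      before$i <- i_next; before$observed[i_next] <- z[i_next]
      eps_before <- model_error(before$modeled[seq_len(i_next)],
                                z[seq_len(i_next)],
                                w, time = rec$time[seq_len(i_next)])
      st <- deconv_step(st, z[i_next])
      eps_after <- model_error(st$modeled[seq_len(i_next)],
                               z[seq_len(i_next)],
                               w, time = rec$time[seq_len(i_next)])
      expect_lte(eps_after, eps_before + 1e-12)
    } else {
      st <- deconv_step(st, z[i_next])
    }
  }
  expect_gt(nrow(st$insert_log), 0L)
})

test_that("a flat noiseless trace deconvolves to zero pulses", {
  res <- run_deconv(flat_recording(10, level = 3))
  expect_equal(nrow(res$pulses), 0L)
  expect_equal(res$modeled$modeled, rep(3, 600))
})

test_that("three noisy pulses are recovered in onset and scale", {
  on <- c(2.0, 4.3, 7.1); sc <- c(0.3, 0.45, 0.2)
  rec <- pulse_recording(on, sc, noise_sd = 0.01, seed = 23)
  res <- run_deconv(rec)
  expect_equal(nrow(res$pulses), 3L)
  for (k in 1:3) {
    j <- which.min(abs(res$pulses$onset_s - on[k]))
    expect_lt(abs(res$pulses$onset_s[j] - on[k]), 0.05)
    expect_lt(abs(res$pulses$scale_mm[j] - sc[k]) / sc[k], 0.1)
  }
})

test_that("deconvolution is deterministic given its inputs", {
  rec <- pulse_recording(c(2, 5), c(0.3, 0.4), noise_sd = 0.01, seed = 24)
  r1 <- run_deconv(rec)
  r2 <- run_deconv(rec)
  expect_identical(r1$pulses, r2$pulses)
  expect_identical(r1$modeled$modeled, r2$modeled$modeled)
  expect_identical(r1$residuals, r2$residuals)
})

test_that("the final modelled trace is the convolution of the final pulses", {
  for (seed in 25:27) {
    rec <- pulse_recording(c(1.5, 3.9, 6.8), c(0.25, 0.5, 0.35),
                           noise_sd = 0.01, seed = seed)
    res <- run_deconv(rec)
    redo <- reconstruct_trace(res$pulses, rec$time, res$params,
                              res$baseline)
    expect_equal(res$modeled$modeled, redo$modeled, tolerance = 1e-9)
  }
})

test_that("run_deconv equals folding deconv_step frame by frame", {
  rec <- pulse_recording(c(1.5, 4.2), c(0.3, 0.4), dur = 8,
                         noise_sd = 0.01, seed = 28)
  cfg <- deconv_config()
  res <- run_deconv(rec, cfg)
  st <- deconv_init(rec$time, cfg, baseline = res$baseline,
                    reference = res$reference)
  for (z in rec$diameter) st <- deconv_step(st, z)
  expect_equal(st$pulses$onset_s, res$candidates$onset_s)
  expect_equal(st$pulses$scale_mm, res$candidates$scale_mm)
  expect_identical(st$residuals, res$residuals)
  expect_identical(st$insert_log, res$insert_log)
})

test_that("raising the threshold never increases the insertion count", {
  rec <- pulse_recording(c(2, 5, 7.5), c(0.3, 0.4, 0.25),
                         noise_sd = 0.01, seed = 29)
  counts <- vapply(c(0.001, 0.0025, 0.005, 0.01), function(f) {
    nrow(run_deconv(rec, deconv_config(threshold_frac = f))$insert_log)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("strongest pulses at the onsets give zero mean offset", {
  ev <- toy_events(data.frame(
    trial_id = rep(1:2, each = 2),
    event = rep(c("memory_array", "response"), 2),
    onset_s = c(2, 3, 6, 7),
    conditions = rep(c("vwm_load=low", "vwm_load=high"), each = 2),
    correct = NA, rt_s = NA))
  pl <- pulse_list(c(2, 6), c(0.4, 0.5))
  off <- strongest_pulse_offsets(pl, ev)
  expect_equal(off$per_event$offset_s, c(0, 0))
  expect_equal(off$summary$mean_offset_s, c(0, 0))
  # planting every pulse 100 ms late shifts the mean by +0.1 s
  pl2 <- pulse_list(c(2.1, 6.1), c(0.4, 0.5))
  off2 <- strongest_pulse_offsets(pl2, ev)
  expect_equal(off2$per_event$offset_s, c(0.1, 0.1), tolerance = 1e-9)
})

test_that("strongest-pulse search matches a brute-force scan", {
  set.seed(30)
  onsets <- sort(runif(40, 0, 100))
  pl <- pulse_list(onsets, runif(40, 0.1, 0.6))
  ev <- toy_events(data.frame(
    trial_id = 1:8, event = "memory_array",
    onset_s = seq(5, 95, length.out = 8),
    conditions = "vwm_load=low", correct = NA, rt_s = NA))
  off <- strongest_pulse_offsets(pl, ev, window_s = 1)
  analysed <- 0L
  for (k in seq_len(nrow(ev))) {
    inwin <- which(abs(pl$onset_s - ev$onset_s[k]) <= 1)
    if (!length(inwin)) next
    analysed <- analysed + 1L
    best <- inwin[which.max(pl$scale_mm[inwin])]
    row <- off$per_event[off$per_event$trial_id == ev$trial_id[k], ]
    expect_equal(row$offset_s, pl$onset_s[best] - ev$onset_s[k])
    expect_equal(row$scale_mm, pl$scale_mm[best])
  }
  expect_equal(nrow(off$per_event), analysed)
  expect_equal(off$n_skipped, nrow(ev) - analysed)
})
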