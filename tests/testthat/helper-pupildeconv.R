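# shared fixture builders (all fixtures are generated in code)

rate_60 <- 60
dt_60 <- 1 / rate_60

# uniform 60-Hz grid of `dur` seconds starting at 0
grid60 <- function(dur) seq(0, dur - dt_60, by = dt_60)

# flat recording with optional additive signal / noise
flat_recording <- function(dur = 10, level = 4.5, signal = 0, noise_sd = 0,
                           confidence = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tm <- grid60(dur)
  d <- rep(level, length(tm)) + signal +
    if (noise_sd > 0) stats::rnorm(length(tm), 0, noise_sd) else 0
  pupil_recording(tm, d, confidence = confidence, rate_hz = rate_60)
}

# recording carrying known pulses above a flat baseline
pulse_recording <- function(onsets, scales, dur = 10, baseline = 4.5,
                            noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tm <- grid60(dur)
  m <- reconstruct_trace(pulse_list(onsets, scales), tm,
                         baseline = baseline)$modeled
  if (noise_sd > 0) m <- m + stats::rnorm(length(tm), 0, noise_sd)
  pupil_recording(tm, m, rate_hz = rate_60)
}

# event log fixture via the text interface (exercises the parser too)
toy_events <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  on.exit(unlink(f))
  read_events(f)
}

# label permutation within participant groups
permute_within <- function(y, g) {
  yp <- y
  for (gg in unique(g)) {
    i <- which(g == gg)
    yp[i] <- sample(y[i])
  }
  yp
}
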