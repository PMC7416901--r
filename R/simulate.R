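#' Simulation configuration
#'
#' Describes a synthetic dual-task session: a 60-Hz recording with a
#' per-trial timeline of fixation, a briefly flashed memory array, a
#' retention interval containing a search array, and a memory probe, with
#' one attentional pulse per stimulus event. Pulse scales carry the
#' condition effects (working-memory load raises the memory-array and
#' probe pulses, search difficulty the search-array pulse); participants
#' get random shifts of both the overall pulse scale and the load effect,
#' which is what makes mixed-model analyses of the cohort meaningful.
#'
#' The defaults mirror the timeline and dilation magnitudes of a
#' laboratory dual-task session at desk scale: pulse scales in the
#' 0.2-0.5 mm range typical of task-evoked dilations, a 0.15-mm
#' working-memory load effect, tonic levels of 5.0 mm (dark background)
#' and 3.2 mm (bright), and clean 0.01-mm measurement noise.
#'
#' @param n_participants participants in a cohort.
#' @param trials_per_condition trials per cell of the factorial design.
#' @param rate_hz sampling rate.
#' @param trial_len_s trial duration including inter-trial interval.
#' @param timeline named numeric vector of stimulus onsets within a trial
#'   (seconds from trial start).
#' @param pulse_scale named list of base pulse scale (mm) per stimulus
#'   event.
#' @param vwm_effect_mm added to memory-array and probe pulse scales under
#'   high working-memory load.
#' @param vs_effect_mm added to the search-array pulse scale under high
#'   search difficulty.
#' @param pulse_jitter_sd sd of pulse-onset jitter around stimulus onset
#'   (seconds).
#' @param scale_trial_sd trial-to-trial sd of pulse scales (mm).
#' @param participant_scale_sd sd of the per-participant overall pulse
#'   scale shift (mm).
#' @param participant_effect_sd sd of the per-participant load-effect
#'   shift (mm).
#' @param tonic_mm named numeric: tonic diameter per luminance level (mm).
#' @param luminance luminance level(s) used; the first is the default for
#'   single-level designs.
#' @param noise_sd measurement noise sd (mm).
#' @param blink_rate_per_min expected blinks per minute (0 disables).
#' @param blink_dur_range blink duration range (seconds).
#' @param rt_meanlog,rt_sdlog lognormal RT parameters (seconds scale).
#' @param accuracy named list: probability of a correct response per
#'   working-memory load level.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 8, trials_per_condition = 4,
                       rate_hz = 60, trial_len_s = 8,
                       timeline = c(memory_array = 1.1,
                                    search_array = 3.26,
                                    memory_probe = 5.46),
                       pulse_scale = list(memory_array = 0.25,
                                          search_array = 0.25,
                                          memory_probe = 0.30),
                       vwm_effect_mm = 0.15, vs_effect_mm = 0.10,
                       pulse_jitter_sd = 0.05, scale_trial_sd = 0.03,
                       participant_scale_sd = 0.05,
                       participant_effect_sd = 0.03,
                       tonic_mm = c(dark = 5.0, bright = 3.2),
                       luminance = "dark",
                       noise_sd = 0.01,
                       blink_rate_per_min = 4,
                       blink_dur_range = c(0.15, 0.3),
                       rt_meanlog = log(0.9), rt_sdlog = 0.25,
                       accuracy = list(low = 0.93, high = 0.67)) {
  stopifnot(n_participants >= 1, trials_per_condition >= 1,
            !is.unsorted(timeline), noise_sd >= 0,
            blink_rate_per_min >= 0, pulse_jitter_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate one participant's recording with known ground truth
#'
#' The diameter stream is `tonic + sum_i s_i h(t - t_i) + noise`, with one
#' attentional pulse per stimulus event, condition effects applied to the
#' pulse scales, and blinks carved out (confidence dropped to zero and the
#' diameter collapsed towards 60% of its local value, a triangular dip —
#' enough to exercise the detector's input contract). Deterministic per
#' seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param participant participant label stored in the outputs.
#' @param participant_shift,participant_effect_shift per-participant
#'   random effects on pulse scale and load effect (drawn by
#'   [simulate_cohort()]; default 0).
#' @return list with `recording` ([pupil_recording()]), `events`
#'   (`event_log`) and `truth` (data.frame of true pulses:
#'   `trial_id`, `event`, `onset_s`, `scale_mm`, plus blink intervals and
#'   baseline as attributes).
#' @export
simulate_recording <- function(config = sim_config(), seed = 1,
                               participant = 1,
                               participant_shift = 0,
                               participant_effect_shift = 0) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  if (max(config$timeline) >= config$trial_len_s)
    stop("trial timeline longer than the trial")
  lum <- config$luminance[1]
  tonic <- config$tonic_mm[[lum]]
  grid_cond <- expand.grid(vwm_load = c("low", "high"),
                           vs_difficulty = c("low", "high"),
                           stringsAsFactors = FALSE)
  cond <- grid_cond[rep(seq_len(nrow(grid_cond)),
                        config$trials_per_condition), , drop = FALSE]
  cond <- cond[sample(nrow(cond)), , drop = FALSE]
  n_trials <- nrow(cond)
  total_s <- n_trials * config$trial_len_s
  tm <- seq(0, total_s - 1 / config$rate_hz, by = 1 / config$rate_hz)
  params <- tepr_params()
  events <- list(); truth <- list()
  m <- numeric(length(tm))
  for (tr in seq_len(n_trials)) {
    t0 <- (tr - 1) * config$trial_len_s
    vwm <- cond$vwm_load[tr]; vs <- cond$vs_difficulty[tr]
    condstr <- sprintf("vwm_load=%s;vs_difficulty=%s;luminance=%s",
                       vwm, vs, lum)
    for (evn in names(config$timeline)) {
      on <- t0 + config$timeline[[evn]]
      s <- config$pulse_scale[[evn]] + participant_shift +
        stats::rnorm(1, 0, config$scale_trial_sd)
      if (evn %in% c("memory_array", "memory_probe") && vwm == "high")
        s <- s + config$vwm_effect_mm + participant_effect_shift
      if (evn == "search_array" && vs == "high")
        s <- s + config$vs_effect_mm
      s <- max(s, 0)
      p_on <- on + stats::rnorm(1, 0, config$pulse_jitter_sd)
      m <- add_pulse_contrib(m, tm, p_on, s, params)
      events[[length(events) + 1L]] <-
        data.frame(trial_id = tr, event = evn, onset_s = on,
                   conditions = condstr, correct = NA, rt_s = NA_real_)
      truth[[length(truth) + 1L]] <-
        data.frame(trial_id = tr, event = evn, onset_s = p_on,
                   scale_mm = s)
    }
    rt <- stats::rlnorm(1, config$rt_meanlog, config$rt_sdlog)
    acc <- config$accuracy[[vwm]]
    events[[length(events) + 1L]] <-
      data.frame(trial_id = tr, event = "response",
                 onset_s = t0 + config$timeline[["memory_probe"]] + rt,
                 conditions = condstr,
                 correct = stats::runif(1) < acc, rt_s = rt)
  }
  d <- tonic + m + stats::rnorm(length(tm), 0, config$noise_sd)
  confidence <- rep(1, length(tm))
  blinks <- data.frame(start = numeric(), end = numeric())
  if (config$blink_rate_per_min > 0) {
    nb <- stats::rpois(1, config$blink_rate_per_min * total_s / 60)
    if (nb > 0) {
      bs <- sort(stats::runif(nb, 0, total_s))
      bd <- stats::runif(nb, config$blink_dur_range[1],
                         config$blink_dur_range[2])
      blinks <- data.frame(start = bs, end = pmin(bs + bd, total_s))
      for (k in seq_len(nb)) {
        idx <- which(tm >= blinks$start[k] & tm <= blinks$end[k])
        if (!length(idx)) next
        mid <- (blinks$start[k] + blinks$end[k]) / 2
        half <- (blinks$end[k] - blinks$start[k]) / 2
        depth <- 1 - 0.4 * (1 - abs(tm[idx] - mid) / half)
        d[idx] <- d[idx] * depth
        confidence[idx] <- 0
      }
    }
  }
  ev <- do.call(rbind, events)
  evfile <- tempfile(fileext = ".csv")
  utils::write.csv(ev, evfile, row.names = FALSE, na = "")
  events_log <- read_events(evfile)
  unlink(evfile)
  rec <- pupil_recording(time = tm, diameter = d, gaze_x = 0, gaze_y = 0,
                         confidence = confidence,
                         rate_hz = config$rate_hz)
  tr <- do.call(rbind, truth)
  attr(tr, "baseline_mm") <- tonic
  attr(tr, "blinks") <- blinks
  attr(tr, "participant") <- participant
  list(recording = rec, events = events_log, truth = tr)
}

#' Simulate a cohort of participants
#'
#' Draws per-participant random effects (overall pulse-scale shift and
#' load-effect shift from the configured normals) and simulates one
#' recording + event log per participant. When `dir` is given, each
#' participant's `recording.csv`, `events.csv` and `truth.csv` are
#' written together with a `manifest.csv`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (participant seeds are derived from it).
#' @param dir optional output directory.
#' @return (invisibly, when writing) list of per-participant simulations
#'   plus a `manifest` data.frame.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1, dir = NULL) {
  set.seed(seed)
  shifts <- stats::rnorm(config$n_participants, 0,
                         config$participant_scale_sd)
  eff_shifts <- stats::rnorm(config$n_participants, 0,
                             config$participant_effect_sd)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2,
                          config$n_participants)
  sims <- lapply(seq_len(config$n_participants), function(p) {
    simulate_recording(config, seed = sub_seeds[p], participant = p,
                       participant_shift = shifts[p],
                       participant_effect_shift = eff_shifts[p])
  })
  manifest <- do.call(rbind, lapply(seq_along(sims), function(p) {
    data.frame(participant = p,
               n_trials = length(unique(sims[[p]]$events$trial_id)),
               n_samples = length(sims[[p]]$recording$time),
               seed = sub_seeds[p])
  }))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in seq_along(sims)) {
      pd <- file.path(dir, sprintf("participant_%02d", p))
      dir.create(pd, showWarnings = FALSE)
      write_recording(sims[[p]]$recording, file.path(pd, "recording.csv"))
      write_events(sims[[p]]$events, file.path(pd, "events.csv"))
      utils::write.csv(sims[[p]]$truth, file.path(pd, "truth.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(list(participants = sims, manifest = manifest))
}

#' Simulate baselined epochs with a known condition effect
#'
#' Directly generates an event-locked, baselined epoch set for a
#' two-level within-participant factor: a constant offset of `effect_mm`
#' over `effect_window` in the high level, per-participant random
#' intercepts and effect slopes, and white measurement noise. This is the
#' generator behind the significance-scan and classification benchmarks,
#' where the effect's true extent must be known exactly.
#'
#' @param n_participants,trials_per_level cohort shape.
#' @param epoch_len_s epoch length (seconds).
#' @param rate_hz sampling rate.
#' @param effect_mm condition effect (mm); the high level adds it inside
#'   the window.
#' @param effect_window `c(start_s, end_s)` of the effect on the epoch
#'   axis.
#' @param noise_sd per-sample noise sd (mm).
#' @param sd_intercept,sd_slope per-participant random intercept / effect
#'   sd (mm).
#' @param factor_name name of the condition column in the metadata.
#' @param seed integer seed.
#' @return an `epoch_set` with metadata columns `participant`, `trial_id`
#'   and the factor.
#' @export
simulate_epochs <- function(n_participants = 20, trials_per_level = 15,
                            epoch_len_s = 2.5, rate_hz = 60,
                            effect_mm = 0.3, effect_window = c(1, 2),
                            noise_sd = 0.05, sd_intercept = 0.02,
                            sd_slope = 0.05, factor_name = "load",
                            seed = 1) {
  set.seed(seed)
  n_samp <- round(epoch_len_s * rate_hz)
  tmv <- (seq_len(n_samp) - 1L) / rate_hz
  win <- as.numeric(tmv >= effect_window[1] & tmv <= effect_window[2])
  rows <- list(); meta <- list()
  for (p in seq_len(n_participants)) {
    b_p <- stats::rnorm(1, 0, sd_intercept)
    u_p <- stats::rnorm(1, 0, sd_slope)
    for (lev in c("low", "high")) {
      x <- as.numeric(lev == "high")
      for (tr in seq_len(trials_per_level)) {
        y <- b_p + (effect_mm + u_p) * x * win +
          stats::rnorm(n_samp, 0, noise_sd)
        rows[[length(rows) + 1L]] <- y
        m <- data.frame(trial_id = length(rows), participant = p,
                        baseline_mm = 0)
        m[[factor_name]] <- lev
        meta[[length(meta) + 1L]] <- m
      }
    }
  }
  new_epoch_set(time = tmv, data = do.call(rbind, rows),
                meta = do.call(rbind, meta), lock_event = "stimulus",
                rate_hz = rate_hz, baseline_s = 0.1)
}

#' Simulate a behavioural table
#'
#' Change-detection style responses: on change trials the participant
#' reports a change with probability `hit_rate`, on no-change trials with
#' probability `fa_rate`; reaction times are lognormal. Supports the
#' behavioural indices (Cowan's K, inverse efficiency, RT filtering)
#' end-to-end.
#'
#' @param n_trials number of trials.
#' @param hit_rate,fa_rate generative hit / false-alarm probabilities.
#' @param change_prob probability a trial contains a change.
#' @param rt_meanlog,rt_sdlog lognormal RT parameters (seconds).
#' @param seed integer seed.
#' @return data.frame: `trial_id`, `change`, `resp_change`, `correct`,
#'   `rt_s`.
#' @export
simulate_behavior <- function(n_trials = 200, hit_rate = 0.9,
                              fa_rate = 0.2, change_prob = 0.5,
                              rt_meanlog = log(0.9), rt_sdlog = 0.25,
                              seed = 1) {
  set.seed(seed)
  change <- stats::runif(n_trials) < change_prob
  resp <- ifelse(change, stats::runif(n_trials) < hit_rate,
                 stats::runif(n_trials) < fa_rate)
  data.frame(trial_id = seq_len(n_trials), change = change,
             resp_change = resp, correct = resp == change,
             rt_s = stats::rlnorm(n_trials, rt_meanlog, rt_sdlog))
}
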