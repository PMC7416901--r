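#' Configuration of the online deconvolution loop
#'
#' The loop watches the residual between the observed diameter and the
#' modelled trace. When the residual exceeds
#' `threshold_frac * reference diameter` (default 0.25% of the recording's
#' median raw diameter) and at least `refractory_s` has passed since the
#' last insertion, a candidate attentional pulse is inserted
#' `back_offset_s` before the detection time stamp and all pulses whose
#' onset lies inside the trailing `opt_window_s` are refit by nonnegative
#' least squares (earlier pulses stay frozen).
#'
#' At the end of a run the candidate list is finalised: candidates whose
#' optimised scale is below `scale_floor_frac` times the detection
#' threshold are discarded, surviving candidates separated by less than
#' `merge_gap_s` are consolidated into one pulse at their scale-weighted
#' mean onset, and each consolidated pulse is refit locally against the
#' full trace.
#'
#' @param threshold_frac residual threshold as a fraction of the reference
#'   diameter.
#' @param back_offset_s back-projection offset from detection time to pulse
#'   onset (seconds).
#' @param refractory_s minimum spacing between insertions (seconds).
#' @param opt_window_s trailing least-squares window (seconds); pulses whose
#'   support ends before it are frozen.
#' @param baseline_mode `"percentile"` (of the 1-s moving-average smoothed
#'   trace, clamped to its minimum) or `"fixed"`.
#' @param baseline_value fixed static baseline in mm (`baseline_mode =
#'   "fixed"`).
#' @param baseline_percentile percentile in `[0, 1]` for percentile mode.
#' @param baseline_smooth_s moving-average width used when estimating the
#'   baseline (seconds).
#' @param scale_floor_frac pulse-retention floor as a multiple of the
#'   detection threshold.
#' @param merge_gap_s candidate-consolidation gap (seconds).
#' @param stale_after_s zero-scale candidates older than this are dropped
#'   from the active set during the run (bookkeeping only; they can no
#'   longer acquire scale once their rise window has passed).
#' @return an object of class `deconv_config`.
#' @export
deconv_config <- function(threshold_frac = 0.0025, back_offset_s = 0.5,
                          refractory_s = 0.1, opt_window_s = 4,
                          baseline_mode = c("percentile", "fixed"),
                          baseline_value = NA_real_,
                          baseline_percentile = 0.01,
                          baseline_smooth_s = 1,
                          scale_floor_frac = 1, merge_gap_s = 0.25,
                          stale_after_s = 1) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(threshold_frac > 0, threshold_frac < 1, back_offset_s > 0,
            refractory_s > 0, opt_window_s > 0,
            baseline_percentile >= 0, baseline_percentile <= 1,
            scale_floor_frac >= 0, merge_gap_s >= 0)
  structure(list(threshold_frac = threshold_frac,
                 back_offset_s = back_offset_s,
                 refractory_s = refractory_s,
                 opt_window_s = opt_window_s,
                 baseline_mode = baseline_mode,
                 baseline_value = baseline_value,
                 baseline_percentile = baseline_percentile,
                 baseline_smooth_s = baseline_smooth_s,
                 scale_floor_frac = scale_floor_frac,
                 merge_gap_s = merge_gap_s,
                 stale_after_s = stale_after_s),
            class = "deconv_config")
}

#' Choose the static baseline for a recording
#'
#' The algorithm assumes a static baseline below the dilation level it
#' models. In percentile mode the baseline is the requested percentile of
#' a 1-s moving-average of the diameter, clamped from above by the minimum
#' of that smoothed trace: the "never exceeds the dilation" requirement is
#' applied to the underlying dilation level, which the smoothed trace
#' estimates, rather than to individual noisy samples (on a noiseless
#' trace the two coincide). Fixed mode returns `baseline_value` as given.
#'
#' @param recording a [pupil_recording()].
#' @param config a [deconv_config()].
#' @return baseline in mm, with attribute `smoothed_min`.
#' @export
choose_baseline <- function(recording, config = deconv_config()) {
  stopifnot(inherits(recording, "pupil_recording"))
  if (config$baseline_mode == "fixed") {
    stopifnot(is.finite(config$baseline_value))
    return(config$baseline_value)
  }
  sm <- moving_average(recording$diameter,
                       max(1L, round(config$baseline_smooth_s *
                                       recording$rate_hz)))
  b <- min(as.numeric(stats::quantile(sm, config$baseline_percentile,
                                      names = FALSE)),
           min(sm))
  attr(b, "smoothed_min") <- min(sm)
  b
}

# centred moving average with shrunken edge windows
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  half <- k %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Initialise online deconvolution state
#'
#' The state carries everything the frame-wise loop needs: the (known)
#' time grid, configuration, static baseline, detection threshold, the
#' active candidate pulse list, the modelled trace implied by it, and the
#' per-frame residual history. `deconv_step()` may only be fed samples in
#' grid order; it never looks ahead in the observed stream, which is what
#' makes the loop online.
#'
#' @param time uniform time grid of the incoming stream (seconds).
#' @param config a [deconv_config()].
#' @param baseline static baseline in mm (see [choose_baseline()]).
#' @param reference reference diameter in mm defining the detection
#'   threshold (`config$threshold_frac * reference`).
#' @param params a [tepr_params()] object.
#' @return an object of class `deconv_state`.
#' @export
deconv_init <- function(time, config = deconv_config(), baseline,
                        reference, params = tepr_params()) {
  stopifnot(is.numeric(time), length(time) >= 2L)
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6) stop("time grid must be uniform")
  n <- length(time)
  structure(list(time = time, dt = stats::median(dt), n = n,
                 config = config, params = params,
                 baseline = as.numeric(baseline),
                 reference = as.numeric(reference),
                 threshold = config$threshold_frac * reference,
                 pulses = data.frame(onset_s = numeric(),
                                     scale_mm = numeric()),
                 modeled = rep(as.numeric(baseline), n),
                 observed = rep(NA_real_, n),
                 residuals = rep(NA_real_, n),
                 i = 0L, last_insert = NA_integer_,
                 insert_log = data.frame(frame = integer(),
                                         t_detect = numeric(),
                                         onset_s = numeric(),
                                         residual_mm = numeric())),
            class = "deconv_state")
}

#' @export
print.deconv_state <- function(x, ...) {
  cat(sprintf("Deconvolution state: frame %d/%d, %d candidate pulse(s), %d insertion(s)\n",
              x$i, x$n, nrow(x$pulses), nrow(x$insert_log)))
  invisible(x)
}

#' Advance the online loop by one observed sample
#'
#' Computes the residual `r = Z[t] - M[t]`; if it exceeds the detection
#' threshold and the refractory period since the last insertion has
#' elapsed, a candidate pulse is inserted at `t - back_offset_s` and
#' [optimize_scales()] is run. Samples must arrive in grid order.
#'
#' @param state a `deconv_state`.
#' @param observed_sample diameter sample in mm for the next frame.
#' @return the advanced state.
#' @export
deconv_step <- function(state, observed_sample) {
  stopifnot(inherits(state, "deconv_state"))
  i <- state$i + 1L
  if (i > state$n) stop("stream ended: no frame left on the grid")
  state$i <- i
  state$observed[i] <- observed_sample
  r <- observed_sample - state$modeled[i]
  state$residuals[i] <- r
  if (r > state$threshold && insertion_allowed(state, i)) {
    state <- insert_pulse(state, i, r)
    state <- optimize_scales(state)
  }
  state
}

insertion_allowed <- function(state, i) {
  is.na(state$last_insert) ||
    (i - state$last_insert) * state$dt >= state$config$refractory_s - 1e-12
}

insert_pulse <- function(state, i, residual) {
  onset <- state$time[i] - state$config$back_offset_s
  state$pulses <- rbind(state$pulses,
                        data.frame(onset_s = onset, scale_mm = 0))
  state$last_insert <- i
  state$insert_log <- rbind(state$insert_log,
                            data.frame(frame = i, t_detect = state$time[i],
                                       onset_s = onset,
                                       residual_mm = residual))
  state
}

#' Refit pulse scales on the trailing window by nonnegative least squares
#'
#' All pulses whose onset lies inside the trailing `opt_window_s` window
#' are free; earlier pulses are frozen and their contribution is
#' subtracted from the target. The free scales are set to the nonnegative
#' least-squares minimiser of the squared error against the observed
#' prefix on the window, so the windowed error never increases across a
#' call. A singular design (e.g., coincident candidate onsets) falls back
#' to a tiny ridge penalty.
#'
#' @param state a `deconv_state` with at least one candidate pulse.
#' @return the state with updated scales and modelled trace.
#' @export
optimize_scales <- function(state) {
  stopifnot(inherits(state, "deconv_state"))
  if (!nrow(state$pulses)) stop("no pulse to optimise")
  i <- state$i
  t_now <- state$time[i]
  w0 <- t_now - state$config$opt_window_s
  widx <- which(state$time >= w0 & seq_len(state$n) <= i)
  # A pulse is free while its onset (hence its rise and peak, the data
  # that identify its scale) lies inside the trailing window; once the
  # window moves past the onset the pulse is frozen, so history that is
  # no longer in evidence can never be unlearned.
  free <- which(state$pulses$onset_s >= w0 & state$pulses$onset_s <= t_now)
  if (!length(free)) return(state)
  tw <- state$time[widx]
  target <- state$observed[widx] - state$baseline
  frozen <- setdiff(seq_len(nrow(state$pulses)), free)
  for (k in frozen) {
    if (state$pulses$scale_mm[k] == 0) next
    target <- target - state$pulses$scale_mm[k] *
      impulse_response(tw - state$pulses$onset_s[k], state$params)
  }
  A <- vapply(free, function(k)
    impulse_response(tw - state$pulses$onset_s[k], state$params),
    numeric(length(widx)))
  A <- matrix(A, nrow = length(widx))
  sol <- tryCatch(pracma::lsqnonneg(A, target)$x,
                  error = function(e) {
                    ridge <- sqrt(1e-8) * diag(ncol(A))
                    pracma::lsqnonneg(rbind(A, ridge),
                                      c(target, numeric(ncol(A))))$x
                  })
  old <- state$pulses$scale_mm[free]
  state$pulses$scale_mm[free] <- sol
  # delta-update the modelled trace for changed pulses only
  for (j in seq_along(free)) {
    d <- sol[j] - old[j]
    if (d != 0)
      state$modeled <- add_pulse_contrib(state$modeled, state$time,
                                         state$pulses$onset_s[free[j]], d,
                                         state$params)
  }
  # zero-scale candidates whose rise window has passed cannot recover
  stale <- state$pulses$scale_mm == 0 &
    state$pulses$onset_s < t_now - state$config$stale_after_s
  if (any(stale)) state$pulses <- state$pulses[!stale, , drop = FALSE]
  state
}

#' Run the online deconvolution over a full recording
#'
#' Equivalent to folding [deconv_step()] over every frame (the insertion
#' rule only fires where the residual crosses the threshold, so the
#' implementation jumps between crossings; the result is identical and
#' bit-for-bit reproducible from the inputs). After the last frame the
#' candidate list is finalised (floor pruning, cluster consolidation,
#' local refit) and the final modelled trace is rebuilt from the final
#' pulses, so `result$modeled` always equals
#' `reconstruct_trace(result$pulses, ...)`.
#'
#' @param recording a preprocessed [pupil_recording()].
#' @param config a [deconv_config()].
#' @param params a [tepr_params()] object.
#' @param reference reference diameter (mm) for the detection threshold;
#'   defaults to the median raw diameter of the recording.
#' @return an object of class `deconv_result`: `pulses` (final
#'   [pulse_list()]), `modeled` (`modeled_trace`), `residuals` (per frame,
#'   as seen online), `candidates` (pre-consolidation pulses),
#'   `insert_log`, `baseline`, `reference`, `config`, `params`.
#' @export
run_deconv <- function(recording, config = deconv_config(),
                       params = tepr_params(), reference = NULL) {
  stopifnot(inherits(recording, "pupil_recording"))
  if (is.null(reference)) reference <- stats::median(recording$diameter)
  baseline <- choose_baseline(recording, config)
  state <- deconv_init(recording$time, config, baseline, reference, params)
  z <- recording$diameter
  state$observed <- z
  refr_frames <- max(1L, as.integer(ceiling(config$refractory_s /
                                              state$dt - 1e-9)))
  i <- 1L
  n <- state$n
  # The modelled trace only changes at insertions, so the frame-wise fold
  # is collapsed into jumps between threshold crossings. Residuals are
  # recorded with the modelled trace as of each frame's processing time,
  # exactly as the per-frame fold would.
  while (i <= n) {
    from <- if (is.na(state$last_insert)) i
            else max(i, state$last_insert + refr_frames)
    if (from > i) {
      upto <- min(from - 1L, n)
      state$residuals[i:upto] <- z[i:upto] - state$modeled[i:upto]
      i <- from
      if (i > n) break
    }
    r_seg <- z[i:n] - state$modeled[i:n]
    hit <- which(r_seg > state$threshold)
    if (!length(hit)) {
      state$residuals[i:n] <- r_seg
      i <- n + 1L
      break
    }
    j <- i + hit[1L] - 1L
    state$residuals[i:j] <- r_seg[seq_len(hit[1L])]
    state$i <- j
    state <- insert_pulse(state, j, r_seg[hit[1L]])
    state <- optimize_scales(state)
    i <- j + 1L
  }
  if (i <= n) state$residuals[i:n] <- z[i:n] - state$modeled[i:n]
  state$i <- n
  finalize_deconv(state, recording)
}

# Floor-prune, consolidate candidate clusters, local refit, rebuild trace.
finalize_deconv <- function(state, recording) {
  cfg <- state$config
  floor_mm <- cfg$scale_floor_frac * state$threshold
  cand <- state$pulses[state$pulses$scale_mm >= floor_mm &
                         state$pulses$scale_mm > 0, , drop = FALSE]
  cand <- cand[order(cand$onset_s), , drop = FALSE]
  if (nrow(cand)) {
    cl <- cumsum(c(1, diff(cand$onset_s) >= cfg$merge_gap_s))
    merged <- do.call(rbind, lapply(split(cand, cl), function(g) {
      data.frame(onset_s = sum(g$onset_s * g$scale_mm) / sum(g$scale_mm),
                 scale_mm = sum(g$scale_mm))
    }))
    # a pulse whose time-to-peak lies beyond the stream end is not yet
    # identifiable (only a sliver of its rise was observed) and stays
    # provisional: it is kept among the candidates but not reported
    t_ident <- max(recording$time) - state$params$t_max
    merged <- merged[merged$onset_s <= t_ident, , drop = FALSE]
    merged <- refit_merged(merged, state, recording)
    merged <- merged[merged$scale_mm >= floor_mm, , drop = FALSE]
  } else {
    merged <- cand
  }
  final <- pulse_list(merged$onset_s, merged$scale_mm)
  modeled <- reconstruct_trace(final, recording$time, state$params,
                               state$baseline)
  structure(list(pulses = final, modeled = modeled,
                 residuals = state$residuals,
                 candidates = pulse_list(state$pulses$onset_s,
                                         state$pulses$scale_mm),
                 insert_log = state$insert_log,
                 baseline = state$baseline, reference = state$reference,
                 threshold = state$threshold,
                 config = state$config, params = state$params),
            class = "deconv_result")
}

# One pass of per-pulse local NNLS against the full trace, other pulses held.
refit_merged <- function(merged, state, recording) {
  tm <- recording$time
  z <- recording$diameter - state$baseline
  support <- state$params$support_s
  contrib <- function(k, idx)
    merged$scale_mm[k] * impulse_response(tm[idx] - merged$onset_s[k],
                                          state$params)
  for (k in seq_len(nrow(merged))) {
    idx <- which(tm > merged$onset_s[k] &
                   tm <= merged$onset_s[k] + support)
    if (!length(idx)) next
    resid <- z[idx]
    for (j in seq_len(nrow(merged)))
      if (j != k) resid <- resid - contrib(j, idx)
    hk <- impulse_response(tm[idx] - merged$onset_s[k], state$params)
    merged$scale_mm[k] <- max(0, sum(hk * resid) / sum(hk * hk))
  }
  merged
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("Online deconvolution result: %d pulse(s) (%d candidates, %d insertions)\n",
              nrow(x$pulses), nrow(x$candidates), nrow(x$insert_log)))
  cat(sprintf("  baseline %.3f mm, reference %.3f mm, threshold %.4f mm\n",
              x$baseline, x$reference, x$threshold))
  invisible(x)
}

#' Timing of the strongest pulse around each stimulus onset
#'
#' For each stimulus event, the pulse with the largest scale within
#' `window_s` seconds of the event onset is located and its temporal
#' offset (pulse onset minus event onset; negative when the pulse precedes
#' the stimulus) recorded. Offsets are averaged within condition groups.
#' Events with no pulse in their window are skipped and counted.
#'
#' @param result a `deconv_result` (or a [pulse_list()]).
#' @param events an `event_log` on the same clock.
#' @param window_s half-width of the search window (seconds).
#' @param group_by character vector of condition factor columns to group
#'   by; defaults to all condition factors in `events`.
#' @param stimulus_events event names to analyse.
#' @return list with `per_event` (one row per analysed event: event,
#'   conditions, offset_s, pulse scale), `summary` (mean offset and count
#'   per event type x condition group) and `n_skipped`.
#' @export
strongest_pulse_offsets <- function(result, events, window_s = 1,
                                    group_by = NULL,
                                    stimulus_events = c("memory_array",
                                                        "search_array",
                                                        "memory_probe")) {
  pulses <- if (inherits(result, "deconv_result")) result$pulses else result
  if (is.null(group_by)) group_by <- condition_factors(events)
  ev <- events[events$event %in% stimulus_events, , drop = FALSE]
  rows <- list(); skipped <- 0L
  for (k in seq_len(nrow(ev))) {
    on <- ev$onset_s[k]
    inwin <- which(abs(pulses$onset_s - on) <= window_s)
    if (!length(inwin)) { skipped <- skipped + 1L; next }
    best <- inwin[which.max(pulses$scale_mm[inwin])]
    r <- data.frame(event = ev$event[k], trial_id = ev$trial_id[k],
                    offset_s = pulses$onset_s[best] - on,
                    scale_mm = pulses$scale_mm[best])
    for (f in group_by) r[[f]] <- ev[[f]][k]
    rows[[length(rows) + 1L]] <- r
  }
  per_event <- if (length(rows)) do.call(rbind, rows)
               else data.frame(event = character(), trial_id = integer(),
                               offset_s = numeric(), scale_mm = numeric())
  if (nrow(per_event)) {
    grp <- per_event[c("event", group_by)]
    agg <- stats::aggregate(per_event$offset_s, grp, mean)
    names(agg)[ncol(agg)] <- "mean_offset_s"
    agg$n <- stats::aggregate(per_event$offset_s, grp, length)$x
  } else {
    agg <- data.frame()
  }
  list(per_event = per_event, summary = agg, n_skipped = skipped)
}
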