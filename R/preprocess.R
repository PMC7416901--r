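#' Detect blink intervals
#'
#' Blinks are taken as maximal runs where sample confidence falls below
#' `conf_threshold` or the sample lies inside a filled raw-clock gap. Runs
#' separated by less than `min_gap_merge` seconds are merged, and every
#' interval is padded by `pad_s` on both sides to cover the partial-lid
#' samples that flank an eyelid closure at 60 Hz. Overlapping intervals are
#' merged after padding, so the result is non-overlapping.
#'
#' @param recording a [pupil_recording()].
#' @param conf_threshold samples with confidence strictly below this are
#'   blink candidates.
#' @param min_gap_merge merge runs separated by less than this (seconds).
#' @param pad_s symmetric padding added to each interval (seconds).
#' @return `data.frame` with columns `start`, `end` (seconds) and `reason`
#'   (`"low_confidence"` or `"clock_gap"`); zero rows when the trace is
#'   clean.
#' @export
detect_blinks <- function(recording, conf_threshold = 0.6,
                          min_gap_merge = 0.05, pad_s = 0.033) {
  stopifnot(inherits(recording, "pupil_recording"))
  low <- recording$confidence < conf_threshold
  gap <- recording$gap_flag & !low
  bad <- low | gap
  empty <- data.frame(start = numeric(), end = numeric(),
                      reason = character())
  if (!any(bad)) return(empty)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  iv <- data.frame(start = recording$time[starts[keep]],
                   end = recording$time[ends[keep]],
                   reason = vapply(keep, function(k) {
                     if (any(low[starts[k]:ends[k]])) "low_confidence"
                     else "clock_gap"
                   }, ""))
  iv <- merge_intervals(iv, min_gap_merge)
  iv$start <- pmax(iv$start - pad_s, recording$time[1])
  iv$end <- pmin(iv$end + pad_s, recording$time[length(recording$time)])
  merge_intervals(iv, 0)
}

# merge intervals whose gap is < tol (tol = 0 merges only overlaps/contacts)
merge_intervals <- function(iv, tol) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in 2:nrow(iv)) {
    j <- nrow(out)
    if (iv$start[k] - out$end[j] < tol ||
        iv$start[k] <= out$end[j]) {
      out$end[j] <- max(out$end[j], iv$end[k])
      if (iv$reason[k] == "low_confidence") out$reason[j] <- "low_confidence"
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Reconstruct blinks by cubic spline interpolation
#'
#' Diameter samples inside each blink interval are replaced by a cubic
#' spline fitted through four anchor samples: the two consecutive samples
#' ending `anchor_offset_s` before the interval start and the two starting
#' `anchor_offset_s` after its end. Anchors are taken outside the padded
#' interval so that partially occluded samples never steer the spline.
#' Samples outside the intervals are untouched. An interval too close to
#' the recording edge for two-sided anchoring falls back to a nearest-value
#' hold (logged in the returned recording's `log` attribute).
#'
#' @param recording a [pupil_recording()].
#' @param intervals as returned by [detect_blinks()].
#' @param anchor_offset_s distance of the nearest anchor from the interval
#'   edge (seconds).
#' @return the recording with repaired diameter.
#' @export
interpolate_blinks <- function(recording, intervals,
                               anchor_offset_s = 0.1) {
  stopifnot(inherits(recording, "pupil_recording"))
  if (NROW(intervals) == 0L) return(recording)
  tm <- recording$time
  d <- recording$diameter
  held <- 0L
  for (k in seq_len(nrow(intervals))) {
    inside <- which(tm >= intervals$start[k] & tm <= intervals$end[k])
    if (!length(inside)) next
    iL <- which(tm <= intervals$start[k] - anchor_offset_s)
    iR <- which(tm >= intervals$end[k] + anchor_offset_s)
    if (length(iL) >= 2L && length(iR) >= 2L) {
      anchors <- c(iL[length(iL) - 1L], iL[length(iL)], iR[1L], iR[2L])
      sf <- stats::splinefun(tm[anchors], d[anchors], method = "fmm")
      d[inside] <- sf(tm[inside])
    } else {
      # edge interval: hold the nearest sample outside the interval
      held <- held + 1L
      before <- which(tm < intervals$start[k])
      after <- which(tm > intervals$end[k])
      fill <- if (length(before)) d[before[length(before)]]
              else if (length(after)) d[after[1L]]
              else stop("blink interval spans the whole recording")
      d[inside] <- fill
    }
  }
  recording$diameter <- d
  lg <- attr(recording, "log")
  if (is.null(lg)) lg <- list()
  lg$n_edge_holds <- held
  attr(recording, "log") <- lg
  recording
}

#' Hampel median filter for despiking
#'
#' For each sample, the median and the median absolute deviation (MAD) of
#' the surrounding `2 * half_window + 1` samples are computed (a five-point
#' window at the default); the sample is replaced by the window median when
#' it deviates from it by more than `n_sigmas * 1.4826 * MAD`. When the
#' window MAD is zero, any deviation from the median is replaced (the limit
#' of the scaled-MAD rule). Edge samples use shrunken windows. The filter
#' is non-recursive: all medians are computed on the input series.
#'
#' @param x numeric series, length >= 5.
#' @param half_window window half-width in samples.
#' @param n_sigmas deviation threshold in robust standard deviations.
#' @return filtered series, same length.
#' @export
hampel_filter <- function(x, half_window = 2, n_sigmas = 3) {
  n <- length(x)
  stopifnot(n >= 5L, is.numeric(x))
  out <- x
  for (i in seq_len(n)) {
    w <- x[max(1L, i - half_window):min(n, i + half_window)]
    med <- stats::median(w)
    mad <- stats::median(abs(w - med))
    dev <- abs(x[i] - med)
    if ((mad == 0 && dev > 0) || dev > n_sigmas * 1.4826 * mad)
      out[i] <- med
  }
  out
}

#' Trial exclusion by gaze eccentricity and blinks near stimulus onsets
#'
#' A trial is excluded when (a) gaze eccentricity
#' \eqn{\sqrt{x^2 + y^2}} exceeds `gaze_limit_deg` at any sample between
#' the first stimulus onset and the (last) response, or (b) any blink
#' interval intersects a window of total width `blink_window_s` centred on
#' any stimulus onset. Trials without a response event are excluded with
#' reason `no_response`.
#'
#' @param recording a [pupil_recording()].
#' @param events an `event_log`.
#' @param blink_intervals from [detect_blinks()].
#' @param gaze_limit_deg eccentricity limit in degrees.
#' @param blink_window_s total (symmetric) window width around each
#'   stimulus onset, seconds.
#' @param stimulus_events event names counting as stimulus onsets.
#' @param response_event event name carrying the response time.
#' @return `data.frame` with `trial_id`, `keep` (logical), `reason`
#'   (`""`, `"gaze"`, `"blink"`, or `"no_response"`).
#' @export
exclude_trials <- function(recording, events, blink_intervals,
                           gaze_limit_deg = 2.8, blink_window_s = 0.3,
                           stimulus_events = c("memory_array",
                                               "search_array",
                                               "memory_probe"),
                           response_event = "response") {
  stopifnot(inherits(recording, "pupil_recording"))
  half <- blink_window_s / 2
  ecc <- sqrt(recording$gaze_x^2 + recording$gaze_y^2)
  ids <- unique(events$trial_id)
  keep <- logical(length(ids))
  reason <- character(length(ids))
  for (k in seq_along(ids)) {
    ev <- events[events$trial_id == ids[k], , drop = FALSE]
    stim <- ev$onset_s[ev$event %in% stimulus_events]
    resp <- ev$onset_s[ev$event == response_event]
    if (!length(resp)) {
      keep[k] <- FALSE; reason[k] <- "no_response"; next
    }
    t0 <- min(stim)
    t1 <- max(resp)
    idx <- recording$time >= t0 & recording$time <= t1
    if (any(ecc[idx] > gaze_limit_deg)) {
      keep[k] <- FALSE; reason[k] <- "gaze"; next
    }
    blink <- FALSE
    if (NROW(blink_intervals)) {
      for (on in stim) {
        if (any(blink_intervals$end >= on - half &
                blink_intervals$start <= on + half)) {
          blink <- TRUE; break
        }
      }
    }
    if (blink) {
      keep[k] <- FALSE; reason[k] <- "blink"
    } else {
      keep[k] <- TRUE; reason[k] <- ""
    }
  }
  data.frame(trial_id = ids, keep = keep, reason = reason)
}

new_epoch_set <- function(time, data, meta, lock_event, rate_hz,
                          baseline_s) {
  stopifnot(is.matrix(data), length(time) == ncol(data),
            nrow(data) == nrow(meta) || nrow(data) == 0L)
  structure(list(time = time, data = data, meta = meta,
                 lock_event = lock_event, rate_hz = rate_hz,
                 baseline_s = baseline_s),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d epoch(s) x %d samples, locked to '%s' (%.4g-%.4g s)\n",
              nrow(x$data), ncol(x$data), x$lock_event,
              if (length(x$time)) min(x$time) else NA,
              if (length(x$time)) max(x$time) else NA))
  invisible(x)
}

#' Cut a recording into baselined, event-locked epochs
#'
#' One epoch per kept (and, by default, correct) trial, locked to the
#' nearest grid sample to the `lock_event` onset. The mean diameter over
#' the `baseline_s` window immediately preceding the onset is subtracted,
#' so epoch values are mm change from baseline. Epochs that would run past
#' the recording end are dropped and counted in the `log` attribute. With
#' zero surviving trials an empty epoch set (not an error) is returned.
#'
#' @param recording a preprocessed [pupil_recording()].
#' @param events an `event_log`.
#' @param lock_event event name to lock to.
#' @param epoch_len_s epoch length in seconds.
#' @param baseline_s baseline window length in seconds (0.1 s = six samples
#'   at 60 Hz).
#' @param keep optional result of [exclude_trials()]; only trials with
#'   `keep == TRUE` are epoched.
#' @param correct_only keep only trials whose response is correct.
#' @param participant optional participant identifier stored per epoch
#'   (needed by [lme_scan()] when sets are combined across participants).
#' @return an `epoch_set`: relative time axis starting at the lock sample,
#'   epoch matrix, and per-epoch metadata (trial id, condition factors,
#'   baseline level in mm).
#' @export
epoch_and_baseline <- function(recording, events, lock_event, epoch_len_s,
                               baseline_s = 0.1, keep = NULL,
                               correct_only = TRUE, participant = NA) {
  stopifnot(inherits(recording, "pupil_recording"))
  tm <- recording$time
  period <- 1 / recording$rate_hz
  n_ep <- round(epoch_len_s * recording$rate_hz)
  fac <- condition_factors(events)
  ids <- unique(events$trial_id)
  if (!is.null(keep)) ids <- intersect(ids, keep$trial_id[keep$keep])
  rows <- list(); meta <- list(); dropped <- 0L
  for (id in ids) {
    ev <- events[events$trial_id == id, , drop = FALSE]
    on <- ev$onset_s[ev$event == lock_event]
    if (!length(on)) next
    on <- on[1]
    if (correct_only) {
      corr <- ev$correct[!is.na(ev$correct)]
      if (!length(corr) || !all(corr)) next
    }
    i0 <- which.min(abs(tm - on))
    if (i0 + n_ep - 1L > length(tm)) { dropped <- dropped + 1L; next }
    bidx <- which(tm >= on - baseline_s & tm < on)
    if (!length(bidx)) { dropped <- dropped + 1L; next }
    b <- mean(recording$diameter[bidx])
    rows[[length(rows) + 1L]] <- recording$diameter[i0:(i0 + n_ep - 1L)] - b
    m <- data.frame(trial_id = id, participant = participant,
                    baseline_mm = b)
    for (f in fac) m[[f]] <- ev[[f]][1]
    meta[[length(meta) + 1L]] <- m
  }
  if (!length(rows)) {
    es <- new_epoch_set(time = (seq_len(n_ep) - 1L) * period,
                        data = matrix(numeric(), 0L, n_ep),
                        meta = data.frame(), lock_event = lock_event,
                        rate_hz = recording$rate_hz,
                        baseline_s = baseline_s)
    attr(es, "log") <- list(n_dropped_truncated = dropped)
    return(es)
  }
  es <- new_epoch_set(time = (seq_len(n_ep) - 1L) * period,
                      data = do.call(rbind, rows),
                      meta = do.call(rbind, meta),
                      lock_event = lock_event,
                      rate_hz = recording$rate_hz,
                      baseline_s = baseline_s)
  attr(es, "log") <- list(n_dropped_truncated = dropped)
  es
}

#' Combine epoch sets (e.g., across participants)
#'
#' Sets must share the time axis, lock event and sampling rate.
#'
#' @param ... `epoch_set` objects.
#' @return a single `epoch_set`.
#' @export
combine_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "epoch_set")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  sets <- Filter(function(s) nrow(s$data) > 0L, sets)
  ref <- sets[[1]]
  for (s in sets[-1]) {
    stopifnot(isTRUE(all.equal(s$time, ref$time)),
              s$lock_event == ref$lock_event)
  }
  new_epoch_set(time = ref$time,
                data = do.call(rbind, lapply(sets, `[[`, "data")),
                meta = do.call(rbind, lapply(sets, `[[`, "meta")),
                lock_event = ref$lock_event, rate_hz = ref$rate_hz,
                baseline_s = ref$baseline_s)
}
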