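#' Construct a pupil recording
#'
#' A continuous diameter/gaze/confidence stream on a strictly increasing,
#' uniform time grid. Diameter is in mm, gaze in degrees of visual angle
#' from screen centre, confidence unitless in `[0, 1]`.
#'
#' @param time numeric, seconds; uniform to within 1e-6 s, length >= 2.
#' @param diameter numeric, mm; must be finite wherever `confidence > 0`.
#' @param gaze_x,gaze_y numeric, degrees; recycled scalars allowed.
#' @param confidence numeric in `[0, 1]`; recycled scalar allowed.
#' @param rate_hz nominal sampling rate; inferred from the grid if `NULL`.
#' @param gap_flag logical per sample: sample lies inside a raw-clock gap
#'   that was filled by interpolation (downstream blink logic treats these
#'   like low-confidence data).
#' @return An object of class `pupil_recording` (a list).
#' @export
pupil_recording <- function(time, diameter, gaze_x = 0, gaze_y = 0,
                            confidence = 1, rate_hz = NULL,
                            gap_flag = FALSE) {
  n <- length(time)
  stopifnot(n >= 2L, is.numeric(time), is.numeric(diameter),
            length(diameter) == n)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time grid must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6)
    stop("time grid must be uniform to within 1e-6 s")
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(dt)
  rec <- list(time = as.numeric(time),
              diameter = as.numeric(diameter),
              gaze_x = rep_len(as.numeric(gaze_x), n),
              gaze_y = rep_len(as.numeric(gaze_y), n),
              confidence = rep_len(as.numeric(confidence), n),
              rate_hz = rate_hz,
              gap_flag = rep_len(as.logical(gap_flag), n))
  if (any(rec$confidence < 0 | rec$confidence > 1, na.rm = TRUE))
    stop("confidence must lie in [0, 1]")
  if (any(!is.finite(rec$diameter[rec$confidence > 0])))
    stop("diameter must be finite wherever confidence > 0")
  class(rec) <- "pupil_recording"
  rec
}

#' @export
print.pupil_recording <- function(x, ...) {
  cat(sprintf("Pupil recording: %d samples at %.6g Hz (%.1f s), diameter %.2f-%.2f mm\n",
              length(x$time), x$rate_hz, diff(range(x$time)),
              min(x$diameter), max(x$diameter)))
  if (any(x$gap_flag))
    cat(sprintf("  %d sample(s) flagged as filled clock gaps\n",
                sum(x$gap_flag)))
  invisible(x)
}

#' Column naming for delimited recording files
#'
#' @param time,diameter,gaze_x,gaze_y,confidence column names in the file.
#'   Gaze and confidence columns are optional: if absent the recording gets
#'   gaze `(0, 0)` and confidence 1.
#' @return a named list used by [read_recording()].
#' @export
pupil_format <- function(time = "time_s", diameter = "diameter_mm",
                         gaze_x = "gaze_x_deg", gaze_y = "gaze_y_deg",
                         confidence = "confidence") {
  list(time = time, diameter = diameter, gaze_x = gaze_x, gaze_y = gaze_y,
       confidence = confidence)
}

#' Read a pupil recording from delimited text and resample to a uniform grid
#'
#' Timestamps are sorted, exact duplicates averaged (their count is kept in
#' the attached log), and every channel is linearly interpolated onto a
#' uniform grid at `rate_hz`. Raw inter-sample gaps longer than two nominal
#' periods are filled by the interpolation but flagged per sample via
#' `gap_flag`, so blink detection can see them.
#'
#' @param path file path; comma-separated with a header row.
#' @param format_spec column naming, see [pupil_format()].
#' @param rate_hz target grid rate; if `NULL`, `1 / median(diff(time))`
#'   rounded to 3 decimals.
#' @return a [pupil_recording()] with attribute `log` (list: `n_raw`,
#'   `n_duplicates`, `n_gap_samples`).
#' @export
read_recording <- function(path, format_spec = pupil_format(),
                           rate_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c("time", "diameter")) {
    if (!format_spec[[col]] %in% names(df))
      stop(sprintf("format error: required column '%s' (%s) missing",
                   format_spec[[col]], col))
  }
  tm <- as.numeric(df[[format_spec$time]])
  if (anyNA(tm)) stop("data error: non-numeric timestamps")
  o <- order(tm)
  df <- df[o, , drop = FALSE]
  tm <- tm[o]
  n_raw <- length(tm)
  # average rows sharing an exact timestamp (deterministic, order-free)
  n_dup <- sum(duplicated(tm))
  if (n_dup > 0) {
    grp <- match(tm, unique(tm))
    num <- vapply(df, is.numeric, logical(1))
    df <- as.data.frame(lapply(seq_along(df), function(j) {
      if (num[j]) as.numeric(tapply(df[[j]], grp, mean))
      else df[[j]][!duplicated(grp)]
    }))
    names(df) <- names(num)
    tm <- unique(tm)
  }
  if (any(diff(tm) <= 0)) stop("data error: non-monotone timestamps")
  if (is.null(rate_hz)) rate_hz <- round(1 / stats::median(diff(tm)), 3)
  period <- 1 / rate_hz
  grid <- seq(tm[1], tm[length(tm)], by = period)
  interp <- function(col, default) {
    nm <- format_spec[[col]]
    if (!nm %in% names(df)) return(rep(default, length(grid)))
    stats::approx(tm, as.numeric(df[[nm]]), xout = grid, rule = 2)$y
  }
  # flag grid samples strictly inside raw gaps > 2 periods
  gap_flag <- rep(FALSE, length(grid))
  gaps <- which(diff(tm) > 2 * period)
  for (g in gaps)
    gap_flag[grid > tm[g] & grid < tm[g + 1]] <- TRUE
  rec <- pupil_recording(time = grid,
                         diameter = interp("diameter", NA_real_),
                         gaze_x = interp("gaze_x", 0),
                         gaze_y = interp("gaze_y", 0),
                         confidence = interp("confidence", 1),
                         rate_hz = rate_hz, gap_flag = gap_flag)
  attr(rec, "log") <- list(n_raw = n_raw, n_duplicates = n_dup,
                           n_gap_samples = sum(gap_flag))
  rec
}

#' Write a pupil recording as delimited text
#'
#' @param rec a [pupil_recording()].
#' @param path output file; columns
#'   `time_s,diameter_mm,gaze_x_deg,gaze_y_deg,confidence`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pupil_recording"))
  df <- data.frame(time_s = fmt_num(rec$time),
                   diameter_mm = fmt_num(rec$diameter),
                   gaze_x_deg = fmt_num(rec$gaze_x),
                   gaze_y_deg = fmt_num(rec$gaze_y),
                   confidence = fmt_num(rec$confidence))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full double precision so text round trips are lossless
fmt_num <- function(x) sprintf("%.17g", x)

#' Read an event log
#'
#' Delimited text with header
#' `trial_id,event,onset_s,conditions,correct,rt_s`, where `conditions`
#' packs factor levels as `factor=level;factor=level`. Unknown factors are
#' preserved as character columns. When `recording` is supplied, events
#' whose onset falls outside the recording span are flagged (column
#' `out_of_span`) with a warning but retained.
#'
#' @param path file path.
#' @param recording optional [pupil_recording()] used for the span check.
#' @return a `data.frame` of class `event_log`: columns `trial_id`, `event`,
#'   `onset_s`, one column per condition factor, `correct`, `rt_s`,
#'   `out_of_span`.
#' @export
read_events <- function(path, recording = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("trial_id", "event", "onset_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("format error: missing column(s) ",
                         paste(miss, collapse = ", "))
  out <- data.frame(trial_id = as.integer(df$trial_id),
                    event = df$event,
                    onset_s = as.numeric(df$onset_s))
  cond <- if ("conditions" %in% names(df)) df$conditions else character(nrow(df))
  fac <- parse_conditions(cond)
  out <- cbind(out, fac)
  out$correct <- if ("correct" %in% names(df))
    as.logical(ifelse(df$correct == "", NA, df$correct))
  else rep(NA, nrow(out))
  out$rt_s <- if ("rt_s" %in% names(df))
    as.numeric(ifelse(df$rt_s == "", NA, df$rt_s))
  else rep(NA_real_, nrow(out))
  out$out_of_span <- rep(FALSE, nrow(out))
  if (!is.null(recording)) {
    span <- range(recording$time)
    bad <- out$onset_s < span[1] | out$onset_s > span[2]
    if (any(bad))
      warning(sprintf("%d event(s) with onset outside the recording span; flagged and retained",
                      sum(bad)))
    out$out_of_span <- bad
  }
  if (nrow(out)) {
    ok <- !unlist(tapply(out$onset_s, out$trial_id,
                         function(x) is.unsorted(x, strictly = FALSE)))
    if (!all(ok)) stop("data error: onsets decrease within a trial")
  }
  class(out) <- c("event_log", "data.frame")
  out
}

parse_conditions <- function(cond) {
  pairs <- lapply(cond, function(s) {
    if (is.na(s) || s == "") return(character())
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  })
  keys <- unique(unlist(lapply(pairs, names)))
  out <- as.data.frame(lapply(keys, function(k)
    vapply(pairs, function(p) if (k %in% names(p)) p[[k]] else NA_character_, "")),
    col.names = keys, optional = TRUE)
  if (!length(keys)) out <- data.frame(row.names = seq_along(cond))
  out
}

#' Write an event log
#'
#' Inverse of [read_events()]; condition factor columns are packed back into
#' the `conditions` field.
#'
#' @param events an `event_log` data.frame.
#' @param path output file.
#' @export
write_events <- function(events, path) {
  fac <- condition_factors(events)
  cond <- if (length(fac)) {
    apply(as.data.frame(events)[fac], 1L, function(r)
      paste(paste0(fac, "=", r), collapse = ";"))
  } else character(nrow(events))
  df <- data.frame(trial_id = events$trial_id, event = events$event,
                   onset_s = fmt_num(events$onset_s), conditions = cond,
                   correct = events$correct, rt_s = events$rt_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Names of the condition factor columns of an event log
#' @param events an `event_log`.
#' @return character vector of factor column names (possibly empty).
#' @export
condition_factors <- function(events) {
  setdiff(names(events), c("trial_id", "event", "onset_s", "correct",
                           "rt_s", "out_of_span"))
}

#' Read / write pulse lists
#'
#' Lossless text round trip of `(onset_s, scale_mm)` pairs at full double
#' precision.
#'
#' @param pulses a [pulse_list()].
#' @param path file path (`onset_s,scale_mm` with header).
#' @return `read_pulses` returns a [pulse_list()].
#' @export
write_pulses <- function(pulses, path) {
  lines <- c("onset_s,scale_mm",
             sprintf("%.17g,%.17g", pulses$onset_s, pulses$scale_mm))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pulses
#' @export
read_pulses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  pulse_list(df$onset_s, df$scale_mm)
}

#' Write / read an epoch set as a pair of delimited files
#'
#' `<stem>_data.csv` holds the epoch matrix (one row per epoch, one column
#' per sample, header giving the relative time axis) and `<stem>_meta.csv`
#' the per-epoch metadata.
#'
#' @param epochs an `epoch_set`, see [epoch_and_baseline()].
#' @param stem path stem for the two files.
#' @return `read_epochs` returns the `epoch_set`.
#' @export
write_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- as.data.frame(apply(epochs$data, 2L, fmt_num))
  if (nrow(epochs$data) == 1L) d <- as.data.frame(t(d))
  names(d) <- sprintf("t%.17g", epochs$time)
  utils::write.csv(d, paste0(stem, "_data.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- epochs$meta
  meta$.lock_event <- epochs$lock_event
  meta$.rate_hz <- epochs$rate_hz
  meta$.baseline_s <- epochs$baseline_s
  utils::write.csv(meta, paste0(stem, "_meta.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  d <- utils::read.csv(paste0(stem, "_data.csv"), check.names = FALSE)
  meta <- utils::read.csv(paste0(stem, "_meta.csv"))
  tm <- as.numeric(sub("^t", "", names(d)))
  lock <- meta$.lock_event[1]
  rate <- meta$.rate_hz[1]
  base_s <- meta$.baseline_s[1]
  meta <- meta[setdiff(names(meta), c(".lock_event", ".rate_hz", ".baseline_s"))]
  new_epoch_set(time = tm, data = as.matrix(d), meta = meta,
                lock_event = lock, rate_hz = rate, baseline_s = base_s)
}
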