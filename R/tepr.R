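#' Impulse-response parameters for the task-evoked pupillary response
#'
#' The task-evoked pupillary response (TEPR) is modelled as an Erlang/gamma
#' kernel \eqn{h(t) = t^{n} e^{-n t / t_{max}}} with shape `n` and
#' time-to-peak `t_max` (the analytic argmax of the kernel). The defaults
#' `n = 10.1` and `t_max = 0.93` s are the empirically established values for
#' cognitively driven pupil dilations.
#'
#' When `normalize_peak` is `TRUE` (the default) the kernel is rescaled to
#' unit peak so that a pulse scale is expressed directly in mm of peak
#' dilation contribution. The kernel's free vertical scale is otherwise
#' absorbed into the pulse scales, so normalisation changes interpretation,
#' not fit.
#'
#' @param n dimensionless shape parameter (> 0).
#' @param t_max time-to-peak in seconds (> 0).
#' @param normalize_peak logical; rescale so that `h(t_max) == 1`.
#' @param support_s finite support used when sampling the kernel for
#'   convolution; beyond `support_s` seconds the (unit-peak) kernel is below
#'   `1e-6` at the default shape and is treated as zero.
#' @return An object of class `tepr_params`.
#' @examples
#' p <- tepr_params()
#' impulse_response(p$t_max, p) # 1 at the peak
#' @export
tepr_params <- function(n = 10.1, t_max = 0.93, normalize_peak = TRUE,
                        support_s = 5) {
  stopifnot(is.numeric(n), length(n) == 1L, n > 0,
            is.numeric(t_max), length(t_max) == 1L, t_max > 0,
            is.logical(normalize_peak), length(normalize_peak) == 1L,
            is.numeric(support_s), length(support_s) == 1L, support_s > 0)
  structure(list(n = n, t_max = t_max, normalize_peak = normalize_peak,
                 support_s = support_s),
            class = "tepr_params")
}

#' @export
print.tepr_params <- function(x, ...) {
  cat(sprintf("TEPR impulse response: h(t) = t^%g exp(-%g t / %g)%s, support %g s\n",
              x$n, x$n, x$t_max,
              if (x$normalize_peak) " (unit peak)" else "", x$support_s))
  invisible(x)
}

#' Evaluate the pupillary impulse response
#'
#' Computes \eqn{h(t) = t^{n} e^{-n t / t_{max}}} (unit-peak rescaled when
#' `params$normalize_peak`), with `h(t) = 0` for `t <= 0`. The function is
#' nonnegative and unimodal with its maximum at `t = t_max`.
#'
#' @param t numeric vector of times in seconds since pulse onset.
#' @param params a [tepr_params()] object.
#' @return numeric vector of kernel amplitudes.
#' @export
impulse_response <- function(t, params = tepr_params()) {
  stopifnot(inherits(params, "tepr_params"), is.numeric(t))
  h <- numeric(length(t))
  pos <- which(t > 0)
  if (length(pos)) {
    u <- t[pos] / params$t_max
    if (params$normalize_peak) {
      # h(t)/h(t_max) = (t/t_max)^n * exp(n (1 - t/t_max)), in log space
      h[pos] <- exp(params$n * (log(u) + 1 - u))
    } else {
      h[pos] <- exp(params$n * (log(t[pos]) - u))
    }
  }
  h
}

#' Construct a pulse list
#'
#' An attentional pulse is a latent point event with onset `t_i` (seconds on
#' the recording clock) and nonnegative scale `s_i` (mm of peak dilation
#' contribution when the kernel is unit-peak normalised). A pulse list is
#' kept sorted by onset.
#'
#' @param onset_s numeric vector of pulse onsets in seconds.
#' @param scale_mm numeric vector of nonnegative pulse scales in mm.
#' @return A `data.frame` of class `pulse_list` with columns `onset_s`,
#'   `scale_mm`, ordered by onset.
#' @export
pulse_list <- function(onset_s = numeric(), scale_mm = numeric()) {
  stopifnot(length(onset_s) == length(scale_mm),
            all(is.finite(onset_s)), all(is.finite(scale_mm)),
            all(scale_mm >= 0))
  o <- order(onset_s)
  structure(data.frame(onset_s = as.numeric(onset_s[o]),
                       scale_mm = as.numeric(scale_mm[o])),
            class = c("pulse_list", "data.frame"))
}

#' @export
print.pulse_list <- function(x, ...) {
  cat(sprintf("Pulse list: %d attentional pulse(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Reconstruct a modelled pupil trace from a pulse list
#'
#' The modelled dilation is the superposition
#' \eqn{M[t] = b + \sum_i s_i h(t - t_i)} of shifted, scaled impulse
#' responses sampled on a uniform time grid, above a static baseline `b`.
#' The kernel is truncated at `params$support_s` seconds, where its
#' amplitude is negligible, so each pulse contributes over a finite window.
#'
#' @param pulses a [pulse_list()] (or data.frame with `onset_s`, `scale_mm`).
#' @param grid uniform numeric time grid in seconds.
#' @param params a [tepr_params()] object.
#' @param baseline static baseline in mm added to the superposition.
#' @return An object of class `modeled_trace`: list with `time`, `modeled`
#'   (mm), `baseline` (mm) and the `params` used.
#' @export
reconstruct_trace <- function(pulses, grid, params = tepr_params(),
                              baseline = 0) {
  stopifnot(is.numeric(grid), length(grid) >= 1L)
  if (length(grid) > 1L) {
    dg <- diff(grid)
    if (max(dg) - min(dg) > 1e-6) stop("`grid` must be uniform")
  }
  m <- rep(as.numeric(baseline), length(grid))
  for (k in seq_len(NROW(pulses))) {
    m <- add_pulse_contrib(m, grid, pulses$onset_s[k], pulses$scale_mm[k],
                           params)
  }
  structure(list(time = grid, modeled = m, baseline = as.numeric(baseline),
                 params = params),
            class = "modeled_trace")
}

# Add scale * h(grid - onset) in place over the kernel's finite support.
add_pulse_contrib <- function(m, grid, onset, scale, params) {
  if (scale == 0) return(m)
  i0 <- findInterval(onset, grid) + 1L       # first grid point > onset
  i1 <- findInterval(onset + params$support_s, grid)
  if (i1 < i0) return(m)
  idx <- i0:i1
  m[idx] <- m[idx] + scale * impulse_response(grid[idx] - onset, params)
  m
}

#' @export
print.modeled_trace <- function(x, ...) {
  cat(sprintf("Modelled pupil trace: %d samples, baseline %.3f mm, peak %.3f mm above baseline\n",
              length(x$time), x$baseline, max(x$modeled - x$baseline)))
  invisible(x)
}

#' Least-squares error between modelled and observed traces
#'
#' The curve-matching objective \eqn{\epsilon = \sum_{t_m \in W} (M[t_m] -
#' Z[t_m])^2} over a time window `W`, in mm^2. Zero iff the traces agree on
#' the window.
#'
#' @param modeled a `modeled_trace` or numeric vector on the same grid as
#'   `observed`.
#' @param observed numeric vector of observed diameters (mm).
#' @param window length-2 numeric `c(start_s, end_s)` on the trace clock, or
#'   `NULL` for the full overlap. The window must contain at least one
#'   sample.
#' @param time time grid; taken from `modeled` when it is a `modeled_trace`.
#' @return nonnegative scalar, mm^2.
#' @export
model_error <- function(modeled, observed, window = NULL, time = NULL) {
  if (inherits(modeled, "modeled_trace")) {
    time <- modeled$time
    modeled <- modeled$modeled
  }
  stopifnot(is.numeric(modeled), is.numeric(observed),
            length(modeled) == length(observed))
  if (is.null(time)) time <- seq_along(modeled)
  idx <- if (is.null(window)) seq_along(modeled)
         else which(time >= window[1] & time <= window[2])
  if (!length(idx)) stop("empty error window")
  sum((modeled[idx] - observed[idx])^2)
}
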