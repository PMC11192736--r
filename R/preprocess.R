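#' Preprocessing configuration
#'
#' The per-trial reduction chain removes the movement-initiation transient,
#' standardises trial length, centres each series around zero and applies a
#' zero-phase Butterworth low-pass.
#'
#' @param trim_s Seconds removed from the start of each trial (default 6).
#' @param target_s Standardised trial length in seconds (default 84).
#' @param cutoff_hz Low-pass cutoff in Hz (default 10).
#' @param filter_order Butterworth order, applied forward-backward so the
#'   effective order is doubled (default 2).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(trim_s = 6, target_s = 84, cutoff_hz = 10,
                              filter_order = 2) {
  stopifnot(trim_s >= 0, target_s > 0, cutoff_hz > 0, filter_order >= 1)
  structure(list(trim_s = trim_s, target_s = target_s, cutoff_hz = cutoff_hz,
                 filter_order = filter_order),
            class = "preprocess_config")
}

#' Remove the initial transient of a trial
#'
#' Drops all samples with `t < trim_s` and re-zeroes the time axis.
#'
#' @param trace A [movement_trace].
#' @param trim_s Seconds to remove from the start.
#' @return The trimmed [movement_trace].
#' @export
trim_transient <- function(trace, trim_s = 6) {
  stopifnot(inherits(trace, "movement_trace"), trim_s >= 0)
  if (trim_s == 0) return(trace)
  if (trace_duration(trace) <= trim_s) {
    stop(sprintf("too short: trial of %.2f s cannot be trimmed by %g s (%s)",
                 trace_duration(trace), trim_s, trace$actor), call. = FALSE)
  }
  keep <- trace$t - trace$t[1] >= trim_s - 1e-12
  movement_trace(trace$t[keep] - trace$t[keep][1], trace$x[keep],
                 fs = trace$fs, trial_id = trace$trial_id, actor = trace$actor)
}

#' Standardise a trace to a fixed duration
#'
#' Longer traces are truncated to the first `target_s` seconds; shorter ones
#' are linearly resampled onto a uniform grid of `round(target_s * fs)`
#' samples spanning `target_s`, so the output duration is `target_s` within
#' one sample period either way.
#'
#' @param trace A [movement_trace].
#' @param target_s Target duration, seconds.
#' @return A [movement_trace] of standardised length.
#' @export
standardize_length <- function(trace, target_s = 84) {
  stopifnot(inherits(trace, "movement_trace"), target_s > 0)
  n_target <- round(target_s * trace$fs)
  n <- length(trace$x)
  if (n >= n_target) {
    movement_trace(trace$t[seq_len(n_target)], trace$x[seq_len(n_target)],
                   fs = trace$fs, trial_id = trace$trial_id,
                   actor = trace$actor)
  } else {
    grid <- seq(0, by = 1 / trace$fs, length.out = n_target)
    # map the available span onto the target grid, then interpolate
    src <- (trace$t - trace$t[1]) * (grid[n_target] / (trace$t[n] - trace$t[1]))
    x <- stats::approx(src, trace$x, xout = grid, rule = 2)$y
    movement_trace(grid, x, fs = trace$fs, trial_id = trace$trial_id,
                   actor = trace$actor)
  }
}

#' Centre a trace around zero
#'
#' @param trace A [movement_trace].
#' @return The mean-subtracted [movement_trace].
#' @export
center_trace <- function(trace) {
  stopifnot(inherits(trace, "movement_trace"))
  movement_trace(trace$t, trace$x - mean(trace$x), fs = trace$fs,
                 trial_id = trace$trial_id, actor = trace$actor)
}

#' Zero-phase Butterworth low-pass
#'
#' Forward-backward filtering ([signal::filtfilt]) so the pass introduces no
#' phase lag; the effective attenuation corresponds to twice the design order.
#'
#' @param trace A [movement_trace].
#' @param cutoff_hz Cutoff frequency, Hz; must be below Nyquist.
#' @param order Butterworth design order (default 2).
#' @return The filtered [movement_trace]; length preserved.
#' @export
lowpass <- function(trace, cutoff_hz = 10, order = 2) {
  stopifnot(inherits(trace, "movement_trace"))
  if (cutoff_hz >= trace$fs / 2) {
    stop(sprintf("config error: cutoff %g Hz is not below Nyquist (%g Hz)",
                 cutoff_hz, trace$fs / 2), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (trace$fs / 2), type = "low")
  y <- signal::filtfilt(bf, trace$x)
  movement_trace(trace$t, y, fs = trace$fs, trial_id = trace$trial_id,
                 actor = trace$actor)
}

#' Apply the full preprocessing chain to a trial pair
#'
#' Per actor: trim the initial transient, standardise the length, centre
#' around zero, low-pass filter. Both output traces have identical length.
#'
#' @param pair A [trial_pair].
#' @param config A [preprocess_config].
#' @return The processed [trial_pair].
#' @export
preprocess_trial <- function(pair, config = preprocess_config()) {
  stopifnot(inherits(pair, "trial_pair"), inherits(config, "preprocess_config"))
  step <- function(trace) {
    trace <- trim_transient(trace, config$trim_s)
    trace <- standardize_length(trace, config$target_s)
    trace <- center_trace(trace)
    lowpass(trace, config$cutoff_hz, config$filter_order)
  }
  p <- step(pair$participant)
  a <- step(pair$avatar)
  if (length(p$x) != length(a$x)) {
    stop("alignment error: processed traces differ in length", call. = FALSE)
  }
  trial_pair(p, a, gaze_condition = pair$gaze_condition,
             coordination = pair$coordination)
}
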