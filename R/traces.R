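#' Construct a movement trace
#'
#' A `movement_trace` is one uniformly sampled 1-D displacement series with
#' its sample rate and trial metadata. It is the unit of currency of the
#' preprocessing and coordination-metric stages.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing on
#'   a uniform grid (tolerance 1e-6 s on the step).
#' @param x Numeric vector of displacement values (arbitrary units), finite,
#'   same length as `t`.
#' @param fs Sample rate in Hz. If `NULL`, inferred from the median time step.
#' @param trial_id Optional trial identifier.
#' @param actor `"participant"` or `"avatar"`.
#' @return An object of class `movement_trace` with fields `t`, `x`, `fs`,
#'   `trial_id`, `actor`.
#' @export
movement_trace <- function(t, x, fs = NULL, trial_id = NA_character_,
                           actor = c("participant", "avatar")) {
  actor <- match.arg(actor)
  if (length(t) != length(x)) {
    stop("`t` and `x` must have the same length", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("empty input: a movement trace needs at least 2 samples",
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("validation error: non-finite displacement values", call. = FALSE)
  }
  steps <- diff(t)
  if (any(steps <= 0)) {
    stop("validation error: `t` must be strictly increasing", call. = FALSE)
  }
  step <- stats::median(steps)
  if (is.null(fs)) fs <- 1 / step
  if (max(abs(steps - step)) > 1e-6) {
    stop("validation error: non-uniform sampling; resample first",
         call. = FALSE)
  }
  structure(
    list(t = as.numeric(t), x = as.numeric(x), fs = fs,
         trial_id = trial_id, actor = actor),
    class = "movement_trace"
  )
}

#' @export
print.movement_trace <- function(x, ...) {
  cat(sprintf("<movement_trace> %s, trial %s: %d samples @ %.6g Hz (%.2f s)\n",
              x$actor, x$trial_id, length(x$x), x$fs,
              length(x$x) / x$fs))
  invisible(x)
}

#' @export
length.movement_trace <- function(x) length(x$x)

trace_duration <- function(trace) length(trace$x) / trace$fs

#' Construct a trial pair
#'
#' Aligned participant and avatar traces for one trial, with the trial's
#' between-participant gaze condition and within-participant coordination
#' condition.
#'
#' @param participant,avatar `movement_trace` objects sharing a sample rate.
#' @param gaze_condition `"direct"` or `"averted"`.
#' @param coordination `"spontaneous"` or `"intentional"`.
#' @return An object of class `trial_pair`.
#' @export
trial_pair <- function(participant, avatar,
                       gaze_condition = c("direct", "averted"),
                       coordination = c("spontaneous", "intentional")) {
  gaze_condition <- match.arg(gaze_condition)
  coordination <- match.arg(coordination)
  stopifnot(inherits(participant, "movement_trace"),
            inherits(avatar, "movement_trace"))
  if (abs(participant$fs - avatar$fs) > 1e-9) {
    stop("alignment error: traces have different sample rates", call. = FALSE)
  }
  structure(
    list(participant = participant, avatar = avatar,
         gaze_condition = gaze_condition, coordination = coordination),
    class = "trial_pair"
  )
}

#' @export
print.trial_pair <- function(x, ...) {
  cat(sprintf("<trial_pair> gaze=%s coordination=%s (%d / %d samples @ %g Hz)\n",
              x$gaze_condition, x$coordination,
              length(x$participant$x), length(x$avatar$x),
              x$participant$fs))
  invisible(x)
}
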