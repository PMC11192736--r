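#' Read a movement trace from CSV
#'
#' Expects columns `t` (seconds) and `x` (displacement). The sample rate is
#' inferred from the median time step; timestamps that deviate from a uniform
#' grid by more than `tol` seconds trigger linear resampling onto the median
#' rate, with a warning.
#'
#' @param path Path to a CSV file with header `t,x`.
#' @param trial_id,actor Metadata attached to the returned trace.
#' @param tol Uniformity tolerance on the time step, seconds.
#' @return A [movement_trace].
#' @export
read_movement_csv <- function(path, trial_id = NA_character_,
                              actor = c("participant", "avatar"),
                              tol = 1e-6) {
  actor <- match.arg(actor)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("t", "x") %in% names(df))) {
    stop("format error: movement CSV must have columns `t` and `x`",
         call. = FALSE)
  }
  if (nrow(df) < 2L) {
    stop("empty input: movement CSV has fewer than 2 rows", call. = FALSE)
  }
  t <- as.numeric(df$t); x <- as.numeric(df$x)
  if (!all(is.finite(x))) {
    stop("validation error: non-finite displacement in ", path, call. = FALSE)
  }
  step <- stats::median(diff(t))
  fs <- 1 / step
  if (max(abs(diff(t) - step)) > tol) {
    grid <- seq(t[1], t[length(t)], by = step)
    x <- stats::approx(t, x, xout = grid, rule = 2)$y
    t <- grid
    warning(sprintf("non-uniform sampling in %s: resampled to %.6g Hz", path, fs),
            call. = FALSE)
  }
  movement_trace(t, x, fs = fs, trial_id = trial_id, actor = actor)
}

#' Read a combined trial-pair CSV
#'
#' Expects columns `t`, `participant`, `avatar` (one trial, both actors on a
#' shared clock).
#'
#' @inheritParams read_movement_csv
#' @param gaze_condition,coordination Condition labels for the trial.
#' @return A [trial_pair].
#' @export
read_pair_csv <- function(path, gaze_condition = c("direct", "averted"),
                          coordination = c("spontaneous", "intentional"),
                          trial_id = NA_character_) {
  gaze_condition <- match.arg(gaze_condition)
  coordination <- match.arg(coordination)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("t", "participant", "avatar")
  if (!all(need %in% names(df))) {
    stop("format error: pair CSV must have columns t,participant,avatar",
         call. = FALSE)
  }
  p <- movement_trace(df$t, df$participant, trial_id = trial_id,
                      actor = "participant")
  a <- movement_trace(df$t, df$avatar, trial_id = trial_id, actor = "avatar")
  trial_pair(p, a, gaze_condition = gaze_condition, coordination = coordination)
}

#' Write a movement trace / trial pair to CSV
#'
#' Emits the dialect the readers consume: UTF-8, comma separator, `.` decimal.
#' @param trace A [movement_trace].
#' @param path Output path.
#' @export
write_movement_csv <- function(trace, path) {
  utils::write.csv(data.frame(t = trace$t, x = trace$x), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_movement_csv
#' @param pair A [trial_pair].
#' @export
write_pair_csv <- function(pair, path) {
  utils::write.csv(
    data.frame(t = pair$participant$t, participant = pair$participant$x,
               avatar = pair$avatar$x),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the per-participant covariate table
#'
#' Columns: `participant_id`, `gaze_condition` (direct/averted), `lsas`, `aq`.
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_covariates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "gaze_condition", "lsas", "aq")
  if (!all(need %in% names(df))) {
    stop("format error: covariates CSV must have columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  bad <- setdiff(unique(df$gaze_condition), c("direct", "averted"))
  if (length(bad)) {
    stop("format error: unknown gaze_condition value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a gaze area-of-interest hit series
#'
#' Columns `t` (seconds) and `aoi`, with `aoi` coded either as labels
#' (`avatar`/`room`/`missing`) or as `1`/`0` (`NA` = missing).
#' @param path CSV path.
#' @return An `aoi_series`: data.frame with `t` and factor `aoi`.
#' @export
read_aoi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t", "aoi") %in% names(df))) {
    stop("format error: AOI CSV must have columns `t` and `aoi`", call. = FALSE)
  }
  aoi_series(df$t, df$aoi)
}
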