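#' Construct a gaze area-of-interest series
#'
#' Per-sample labels classifying gaze as on the avatar, elsewhere in the
#' room, or missing (blinks, tracking loss). Numeric input is mapped
#' 1 -> avatar, 0 -> room, NA -> missing.
#'
#' @param t Sample times, seconds, non-decreasing.
#' @param aoi Character labels (`avatar`/`room`/`missing`) or 0/1/NA codes.
#' @return An `aoi_series`: data.frame with columns `t` and `aoi` (factor).
#' @export
aoi_series <- function(t, aoi) {
  if (is.numeric(aoi) || is.logical(aoi)) {
    lab <- ifelse(is.na(aoi), "missing", ifelse(aoi == 1, "avatar", "room"))
  } else {
    lab <- as.character(aoi)
    lab[is.na(lab)] <- "missing"
  }
  bad <- setdiff(unique(lab), c("avatar", "room", "missing"))
  if (length(bad)) {
    stop("format error: unknown AOI label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(t)) {
    stop("validation error: AOI times must be non-decreasing", call. = FALSE)
  }
  structure(
    data.frame(t = as.numeric(t),
               aoi = factor(lab, levels = c("avatar", "room", "missing"))),
    class = c("aoi_series", "data.frame"))
}

#' Proportion of a trial spent looking at the avatar
#'
#' Under the default `exclude` policy missing samples are dropped from the
#' denominator (valid-tracking time); under `as_room` they count as
#' not-on-avatar (total trial time).
#'
#' @param series An `aoi_series` (see [aoi_series], [read_aoi_csv]).
#' @param missing_policy `"exclude"` (default) or `"as_room"`.
#' @param window Optional `c(t_lo, t_hi)` restriction in seconds, applied
#'   before counting (e.g. the 6-90 s analysis window of the movement data).
#' @return Proportion in \[0, 1\].
#' @export
gaze_proportion <- function(series, missing_policy = c("exclude", "as_room"),
                            window = NULL) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(series, "aoi_series"))
  aoi <- series$aoi
  if (!is.null(window)) {
    keep <- series$t >= window[1] & series$t < window[2]
    aoi <- aoi[keep]
  }
  if (length(aoi) == 0) {
    stop("empty input: no AOI samples in the requested window", call. = FALSE)
  }
  n_avatar <- sum(aoi == "avatar")
  denom <- switch(missing_policy,
                  exclude = sum(aoi != "missing"),
                  as_room = length(aoi))
  if (denom == 0) {
    stop("undefined proportion: all AOI samples are missing", call. = FALSE)
  }
  n_avatar / denom
}
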