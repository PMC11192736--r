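#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x Numeric vector (centred, band-limited).
#' @return Complex vector `x + i * H(x)`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a movement trace
#'
#' Phase is the angle of the analytic signal. Because the Hilbert transform
#' is unreliable near the series ends, the first and last `edge_discard_s`
#' seconds are flagged (attribute `keep`) for exclusion from downstream
#' statistics; the phase itself is returned in full.
#'
#' @param trace A [movement_trace] (centred, band-limited).
#' @param edge_discard_s Seconds flagged at each end (default 1).
#' @return Numeric vector of wrapped phase in radians, with logical
#'   attribute `keep` marking interior samples.
#' @export
instantaneous_phase <- function(trace, edge_discard_s = 1) {
  stopifnot(inherits(trace, "movement_trace"))
  if (all(trace$x == 0)) {
    stop("degenerate signal: all-zero trace has no phase", call. = FALSE)
  }
  phase <- Arg(analytic_signal(trace$x))
  n <- length(phase)
  k <- min(round(edge_discard_s * trace$fs), floor((n - 1) / 2))
  keep <- rep(TRUE, n)
  if (k > 0) keep[c(seq_len(k), n - seq_len(k) + 1)] <- FALSE
  attr(phase, "keep") <- keep
  phase
}

wrap_degrees <- function(deg) {
  out <- (deg + 180) %% 360 - 180
  # map -180 to the representative +180 so the range is (-180, 180]
  out[out == -180] <- 180
  out
}

#' Relative phase between participant and avatar
#'
#' Signed relative phase is the wrapped difference participant - avatar in
#' degrees on (-180, 180]; the folded series is its absolute value on
#' \[0, 180\], the descriptive convention of the coordination literature.
#'
#' @param p_phase,a_phase Phase series in radians (equal length); `keep`
#'   attributes, if present, are combined.
#' @return A `relative_phase_series` with fields `phi_signed`, `phi_folded`
#'   (degrees) and `keep`.
#' @export
relative_phase <- function(p_phase, a_phase) {
  if (length(p_phase) != length(a_phase)) {
    stop("alignment error: phase series lengths differ", call. = FALSE)
  }
  keep_p <- attr(p_phase, "keep") %||% rep(TRUE, length(p_phase))
  keep_a <- attr(a_phase, "keep") %||% rep(TRUE, length(a_phase))
  phi <- wrap_degrees((as.numeric(p_phase) - as.numeric(a_phase)) * 180 / pi)
  structure(list(phi_signed = phi, phi_folded = abs(phi),
                 keep = keep_p & keep_a),
            class = "relative_phase_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coordination stability rho
#'
#' The mean resultant length of the signed relative-phase distribution:
#' `|mean(exp(i * phi))|`, ranging from 0 (no synchronisation) to 1 (perfect
#' phase locking). Computed on the signed phase: folding first would score a
#' balanced mixture of +90 and -90 degrees as perfectly locked.
#'
#' @param series A `relative_phase_series`, or a numeric vector of signed
#'   phase values in degrees.
#' @param use_keep Honour the series' edge-discard flags (default TRUE).
#' @return rho in \[0, 1\].
#' @export
phase_rho <- function(series, use_keep = TRUE) {
  if (inherits(series, "relative_phase_series")) {
    phi <- if (use_keep) series$phi_signed[series$keep] else series$phi_signed
  } else {
    phi <- as.numeric(series)
  }
  if (length(phi) == 0) {
    stop("empty input: no phase samples to summarise", call. = FALSE)
  }
  Mod(mean(exp(1i * phi * pi / 180)))
}

#' Fisher transformation of rho
#'
#' `atanh` after clipping at `1 - eps` so perfect synchrony stays finite.
#'
#' @param rho Value(s) in \[0, 1\].
#' @param eps Clipping constant (default 1e-6).
#' @return Transformed value(s) on the unbounded non-negative scale.
#' @export
fisher_z <- function(rho, eps = 1e-6) {
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1)) {
    stop("domain error: rho must lie in [0, 1]", call. = FALSE)
  }
  atanh(pmin(rho, 1 - eps))
}

#' Phase metrics for a processed trial pair
#'
#' Convenience wrapper: instantaneous phases, relative phase, rho and its
#' Fisher transformation.
#'
#' @param pair A processed [trial_pair].
#' @param edge_discard_s Seconds flagged at each series end (default 1).
#' @return List with `series` (the relative-phase series), `rho`, `rho_z`.
#' @export
dyad_phase_metrics <- function(pair, edge_discard_s = 1) {
  pp <- instantaneous_phase(pair$participant, edge_discard_s)
  ap <- instantaneous_phase(pair$avatar, edge_discard_s)
  series <- relative_phase(pp, ap)
  rho <- phase_rho(series)
  list(series = series, rho = rho, rho_z = fisher_z(rho))
}
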