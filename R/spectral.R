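#' Spectral configuration for coherence estimation
#'
#' Welch parameters and the analysis band over which the weighted-average
#' coherence is taken. Defaults resolve the 1.4 Hz movement frequency with
#' roughly 20 s Hann segments at 50 Hz and restrict the average to the band
#' where arm-movement energy can lie after the 10 Hz low-pass.
#'
#' @param nperseg Segment length, samples (default 1024).
#' @param overlap Fractional segment overlap in \[0, 1) (default 0.5).
#' @param band Frequency band `c(f_lo, f_hi)` in Hz (default `c(0.2, 10)`).
#' @param weights `"autopower"` (mean auto-power of the two signals, the
#'   default), `"crosspower"` (cross-spectral magnitude) or `"flat"`.
#' @return A `spectral_config` list.
#' @export
spectral_config <- function(nperseg = 1024, overlap = 0.5,
                            band = c(0.2, 10),
                            weights = c("autopower", "crosspower", "flat")) {
  weights <- match.arg(weights)
  stopifnot(nperseg >= 8, overlap >= 0, overlap < 1,
            length(band) == 2, band[1] >= 0, band[2] > band[1])
  structure(list(nperseg = nperseg, overlap = overlap, band = band,
                 weights = weights),
            class = "spectral_config")
}

#' Welch-averaged cross-spectra and magnitude-squared coherence
#'
#' Hann-tapered overlapping segments; auto- and cross-spectral densities are
#' averaged across segments before forming
#' `coh(f) = |Pxy|^2 / (Pxx * Pyy)`. Per-frequency weights are restricted to
#' the analysis band and normalised to sum to one.
#'
#' @param x,y Equal-length numeric vectors (processed traces), or
#'   [movement_trace] objects.
#' @param fs Sample rate in Hz (taken from `x` if it is a trace).
#' @param config A [spectral_config].
#' @return A `spectral_estimate`: list with `freqs`, `coh`, `weight`,
#'   `band`, `n_segments` (fields restricted to the band).
#' @export
cross_spectra <- function(x, y, fs = NULL, config = spectral_config()) {
  if (inherits(x, "movement_trace")) { fs <- x$fs; x <- x$x }
  if (inherits(y, "movement_trace")) { y <- y$x }
  if (is.null(fs)) stop("config error: sample rate `fs` required", call. = FALSE)
  if (length(x) != length(y)) {
    stop("alignment error: input lengths differ", call. = FALSE)
  }
  n <- length(x)
  nseg <- config$nperseg
  if (n < nseg) {
    stop(sprintf("too short: %d samples < one %d-sample segment", n, nseg),
         call. = FALSE)
  }
  step <- max(1L, round(nseg * (1 - config$overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  nf <- floor(nseg / 2) + 1L
  pxx <- pyy <- numeric(nf)
  pxy <- complex(nf)
  for (s in starts) {
    seg <- s:(s + nseg - 1L)
    X <- stats::fft((x[seg] - mean(x[seg])) * win)[seq_len(nf)]
    Y <- stats::fft((y[seg] - mean(y[seg])) * win)[seq_len(nf)]
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  m <- length(starts)
  pxx <- pxx / m; pyy <- pyy / m; pxy <- pxy / m
  freqs <- (seq_len(nf) - 1L) * fs / nseg
  denom <- pxx * pyy
  coh <- ifelse(denom > 0, Mod(pxy)^2 / denom, 0)
  coh <- pmin(pmax(coh, 0), 1)
  in_band <- freqs >= config$band[1] & freqs <= config$band[2] & freqs > 0
  if (!any(in_band)) {
    stop("config error: analysis band contains no frequency bins",
         call. = FALSE)
  }
  # auto-power weights use band-normalised spectra so the weighting (and
  # hence the coherence average) is invariant to rescaling either input
  w <- switch(config$weights,
              autopower  = (pxx / sum(pxx[in_band]) +
                              pyy / sum(pyy[in_band])) / 2,
              crosspower = Mod(pxy) / sum(Mod(pxy)[in_band]),
              flat       = rep(1, nf))
  w[!in_band] <- 0
  if (sum(w) <= 0) w[in_band] <- 1
  w <- w / sum(w)
  structure(list(freqs = freqs[in_band], coh = coh[in_band],
                 weight = w[in_band] / sum(w[in_band]),
                 band = config$band, n_segments = m),
            class = "spectral_estimate")
}

#' Weighted average cross-spectral coherence
#'
#' The frequency-matching index: `sum(weight * coh)` over the analysis band,
#' in \[0, 1\], 1 meaning perfect coordination of movement frequency.
#'
#' @param spec A `spectral_estimate` from [cross_spectra].
#' @return Scalar coherence in \[0, 1\].
#' @export
weighted_coherence <- function(spec) {
  stopifnot(inherits(spec, "spectral_estimate"))
  if (length(spec$coh) == 0) {
    stop("config error: empty analysis band", call. = FALSE)
  }
  sum(spec$weight * spec$coh)
}
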