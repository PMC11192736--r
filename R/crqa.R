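#' CRQA parameter bundle
#'
#' @param delay Embedding delay in samples (>= 1).
#' @param dim Embedding dimension (>= 1).
#' @param radius Neighbourhood radius, in pooled-SD units of the z-scored
#'   series; `NULL` means "tune to `target_rr`".
#' @param min_line Minimum diagonal line length counted by MaxLine
#'   (default 2).
#' @param target_rr Target recurrence rate, percent (default 5).
#' @return A `crqa_params` list.
#' @export
crqa_params <- function(delay = NULL, dim = NULL, radius = NULL,
                        min_line = 2, target_rr = 5) {
  stopifnot(is.null(delay) || delay >= 1, is.null(dim) || dim >= 1,
            is.null(radius) || radius > 0, min_line >= 2,
            target_rr > 0, target_rr < 100)
  structure(list(delay = delay, dim = dim, radius = radius,
                 min_line = min_line, target_rr = target_rr),
            class = "crqa_params")
}

#' Average mutual information curve
#'
#' Mutual information (bits) between `x(t)` and `x(t + tau)` for
#' `tau = 0..max_lag`, from an equal-width joint histogram with
#' `ceiling(sqrt(N - tau))` bins per margin, capped at `bins_max`. Its first
#' minimum is the standard choice of embedding delay.
#'
#' @param x Numeric vector, non-constant.
#' @param max_lag Largest lag, samples.
#' @param bins_max Cap on the number of histogram bins (default 64).
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag), in bits.
#' @export
average_mutual_information <- function(x, max_lag, bins_max = 64) {
  x <- as.numeric(x)
  N <- length(x)
  stopifnot(max_lag >= 1, N > max_lag + 1)
  if (diff(range(x)) == 0) {
    stop("degenerate signal: constant series has no mutual information",
         call. = FALSE)
  }
  rng <- range(x)
  vapply(0:max_lag, function(tau) {
    n <- N - tau
    nb <- min(ceiling(sqrt(n)), bins_max)
    brk <- seq(rng[1], rng[2], length.out = nb + 1)
    a <- findInterval(x[seq_len(n)], brk, rightmost.closed = TRUE,
                      all.inside = TRUE)
    b <- findInterval(x[seq_len(n) + tau], brk, rightmost.closed = TRUE,
                      all.inside = TRUE)
    joint <- tabulate(a + nb * (b - 1L), nbins = nb * nb) / n
    pa <- tabulate(a, nbins = nb) / n
    pb <- tabulate(b, nbins = nb) / n
    pij <- matrix(joint, nb, nb)
    pr <- outer(pa, pb)
    nz <- pij > 0
    sum(pij[nz] * log2(pij[nz] / pr[nz]))
  }, numeric(1))
}

#' First-minimum delay selection from an AMI curve
#'
#' Returns the smallest lag `tau >= 1` that is a local minimum of the curve
#' (`ami(tau) < ami(tau - 1)` and `ami(tau) <= ami(tau + 1)`). If the curve
#' has no interior local minimum, the global minimum over `tau >= 1` is
#' returned with a warning.
#'
#' @param ami_curve Numeric vector over lags `0..max_lag` (as returned by
#'   [average_mutual_information]).
#' @return Integer delay in samples.
#' @export
select_delay <- function(ami_curve) {
  stopifnot(length(ami_curve) >= 3)
  L <- length(ami_curve) - 1L  # max lag
  for (tau in 1:(L - 1L)) {
    if (ami_curve[tau + 1L] < ami_curve[tau] &&
        ami_curve[tau + 1L] <= ami_curve[tau + 2L]) {
      return(tau)
    }
  }
  warning("no local AMI minimum found; using the global minimum",
          call. = FALSE)
  which.min(ami_curve[-1L])
}

#' False-nearest-neighbour fractions per embedding dimension
#'
#' Kennel criterion: for each candidate dimension `d`, each point's nearest
#' neighbour in the `d`-dimensional delay embedding is tested with the
#' `(d+1)`-th coordinate; the neighbour is false when the distance-increase
#' ratio exceeds `rtol` or the grown distance exceeds `atol` times the
#' series SD.
#'
#' @param x Numeric vector.
#' @param delay Embedding delay, samples.
#' @param max_dim Largest dimension tested.
#' @param rtol Distance-increase ratio threshold (default 15).
#' @param atol Absolute-size threshold in series-SD units (default 2).
#' @return Numeric vector of FNN fractions for dimensions `1..max_dim`
#'   (`NA` where the series is too short to test).
#' @export
false_nearest_neighbours <- function(x, delay, max_dim = 10, rtol = 15,
                                     atol = 2) {
  x <- as.numeric(x)
  stopifnot(delay >= 1, max_dim >= 1)
  if (length(x) <= delay + 1) {
    stop("too short: cannot embed at the requested delay", call. = FALSE)
  }
  cpp_fnn(x, as.integer(delay), as.integer(max_dim), rtol,
          atol * stats::sd(x))
}

#' First-minimum embedding-dimension selection from an FNN curve
#'
#' First local minimum of the FNN fraction; if none, the first dimension
#' with fraction below `thresh`; failing that, the global minimum with a
#' warning.
#'
#' @param fnn_curve Numeric vector of fractions for dimensions `1..max_dim`.
#' @param thresh Fall-back threshold on the fraction (default 0.01).
#' @return Integer embedding dimension.
#' @export
select_embedding_dim <- function(fnn_curve, thresh = 0.01) {
  f <- fnn_curve[!is.na(fnn_curve)]
  stopifnot(length(f) >= 1)
  if (length(f) >= 3) {
    for (d in 2:(length(f) - 1L)) {
      if (f[d] < f[d - 1L] && f[d] <= f[d + 1L]) return(d)
    }
  }
  below <- which(f < thresh)
  if (length(below)) return(below[1])
  warning("no FNN minimum below threshold; using the global minimum",
          call. = FALSE)
  which.min(f)
}

#' Time-delay embedding
#'
#' @param x Numeric vector of length `N > (dim - 1) * delay`.
#' @param dim Embedding dimension.
#' @param delay Delay, samples.
#' @return Numeric matrix with `N - (dim - 1) * delay` rows (delay vectors)
#'   and `dim` columns.
#' @export
embed_series <- function(x, dim, delay) {
  x <- as.numeric(x)
  N <- length(x)
  stopifnot(dim >= 1, delay >= 1)
  n <- N - (dim - 1L) * delay
  if (n < 1) {
    stop("too short: need N > (dim - 1) * delay samples", call. = FALSE)
  }
  out <- matrix(0, n, dim)
  for (k in seq_len(dim)) {
    out[, k] <- x[seq_len(n) + (k - 1L) * delay]
  }
  out
}

#' Dense cross-recurrence matrix
#'
#' `R[i, j] = 1` when the Euclidean distance between embedded point `i` of
#' the first series and point `j` of the second is at most `radius`. Use
#' [crqa_stats] for long series; this materialises the full matrix.
#'
#' @param ex,ey Embedding matrices (shared column count).
#' @param radius Neighbourhood radius.
#' @return Integer 0/1 matrix, `nrow(ex)` x `nrow(ey)`.
#' @export
cross_recurrence_matrix <- function(ex, ey, radius) {
  ex <- as.matrix(ex); ey <- as.matrix(ey)
  if (ncol(ex) != ncol(ey)) {
    stop("alignment error: embedding dimensions differ", call. = FALSE)
  }
  stopifnot(radius > 0)
  cpp_recurrence_matrix(ex, ey, radius)
}

#' Recurrence rate of a recurrence matrix
#'
#' @param R A 0/1 recurrence matrix.
#' @return Percentage of recurrent cells in \[0, 100\].
#' @export
recurrence_rate <- function(R) {
  if (length(R) == 0) stop("empty input: empty recurrence matrix",
                           call. = FALSE)
  100 * sum(R) / length(R)
}

#' Longest diagonal line (MaxLine)
#'
#' Length of the longest run of consecutive recurrent points along any
#' diagonal of the matrix; runs shorter than `min_line` count as zero.
#' All diagonals are included: a cross-recurrence plot between distinct
#' signals has no trivial identity line to exclude.
#'
#' @param R A 0/1 recurrence matrix.
#' @param min_line Minimum countable run length (default 2).
#' @return Integer MaxLine in samples (0 when no run reaches `min_line`).
#' @export
max_line <- function(R, min_line = 2) {
  R <- as.matrix(R)
  nx <- nrow(R); ny <- ncol(R)
  best <- 0L
  for (off in (-(nx - 1L)):(ny - 1L)) {
    i <- if (off < 0) -off + 1L else 1L
    j <- if (off < 0) 1L else off + 1L
    len <- min(nx - i + 1L, ny - j + 1L)
    d <- R[cbind(i + seq_len(len) - 1L, j + seq_len(len) - 1L)]
    r <- rle(d)
    runs <- r$lengths[r$values == 1]
    if (length(runs) && max(runs) > best) best <- max(runs)
  }
  if (best < min_line) 0L else as.integer(best)
}

#' Recurrence statistics without materialising the matrix
#'
#' Computes the recurrence rate and MaxLine of the cross-recurrence matrix
#' by streaming over its diagonals in compiled code; identical in value to
#' [recurrence_rate] / [max_line] on the dense matrix.
#'
#' @inheritParams cross_recurrence_matrix
#' @param min_line Minimum countable diagonal run (default 2).
#' @return List with `rec_pct`, `maxline`, `count`.
#' @export
crqa_stats <- function(ex, ey, radius, min_line = 2) {
  ex <- as.matrix(ex); ey <- as.matrix(ey)
  if (ncol(ex) != ncol(ey)) {
    stop("alignment error: embedding dimensions differ", call. = FALSE)
  }
  cpp_rec_stats(ex, ey, radius, as.integer(min_line))
}

#' Tune the radius to a target recurrence rate
#'
#' Bisection on the radius, exploiting the exact monotonicity of the
#' recurrence rate in the radius. Succeeds when a radius is found whose
#' recurrence rate lies within `tol` percentage points of `target_rr`.
#'
#' @param ex,ey Embedding matrices.
#' @param target_rr Target recurrence rate, percent (default 5).
#' @param tol Tolerance, percentage points (default 0.5).
#' @param max_iter Iteration cap (default 60).
#' @return List with `radius`, `rec_pct`, `iterations`.
#' @export
tune_radius <- function(ex, ey, target_rr = 5, tol = 0.5, max_iter = 60) {
  ex <- as.matrix(ex); ey <- as.matrix(ey)
  stopifnot(target_rr > 0, target_rr < 100 || target_rr == 100, tol > 0)
  hi <- cpp_max_pairwise_dist(ex, ey) * (1 + 1e-12)  # guard sqrt round-trip
  if (hi == 0) {
    stop("tuning error: all embedded points coincide", call. = FALSE)
  }
  rr_at <- function(r) cpp_rec_stats(ex, ey, r, 2L)$rec_pct
  rr_hi <- rr_at(hi)  # = 100 by construction
  if (abs(rr_hi - target_rr) <= tol) {
    return(list(radius = hi, rec_pct = rr_hi, iterations = 1L))
  }
  lo <- 0; best_r <- hi; best_rr <- rr_hi
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    rr <- rr_at(mid)
    if (abs(rr - target_rr) < abs(best_rr - target_rr)) {
      best_r <- mid; best_rr <- rr
    }
    if (abs(rr - target_rr) <= tol) {
      return(list(radius = mid, rec_pct = rr, iterations = it))
    }
    if (rr > target_rr) hi <- mid else lo <- mid
  }
  stop(sprintf(
    "tuning error: target %.3g%% unattainable within %d iterations (closest %.3g%% at radius %.4g)",
    target_rr, max_iter, best_rr, best_r), call. = FALSE)
}

#' Estimate embedding parameters for one series
#'
#' AMI first minimum for the delay, FNN first minimum for the dimension.
#'
#' @param x Numeric vector.
#' @param max_lag Largest AMI lag (default 100 samples).
#' @param max_dim Largest FNN dimension (default 10).
#' @return List with `delay`, `dim`, plus the `ami` and `fnn` curves.
#' @export
estimate_embedding <- function(x, max_lag = 100, max_dim = 10) {
  ami <- average_mutual_information(x, max_lag)
  delay <- select_delay(ami)
  fnn <- false_nearest_neighbours(x, delay, max_dim)
  dim <- select_embedding_dim(fnn)
  list(delay = delay, dim = dim, ami = ami, fnn = fnn)
}

#' Cross-recurrence metrics for a processed trial pair
#'
#' Both series are z-scored (so the radius is in pooled-SD units), embedded
#' with the supplied or estimated `(dim, delay)`, and either analysed at the
#' fixed radius or at the radius tuned to the target recurrence rate.
#'
#' @param pair A processed [trial_pair].
#' @param params A [crqa_params]; `NULL` fields are estimated per trial.
#' @param max_lag,max_dim Search ranges for the parameter estimation.
#' @return List with `rec_pct`, `maxline`, `radius_used`, `delay`, `dim`.
#' @export
dyad_crqa_metrics <- function(pair, params = crqa_params(),
                              max_lag = 100, max_dim = 10) {
  x <- as.numeric(scale(pair$participant$x))
  y <- as.numeric(scale(pair$avatar$x))
  delay <- params$delay
  dim <- params$dim
  if (is.null(delay) || is.null(dim)) {
    est_x <- estimate_embedding(x, max_lag, max_dim)
    est_y <- estimate_embedding(y, max_lag, max_dim)
    if (is.null(delay)) delay <- round(stats::median(c(est_x$delay, est_y$delay)))
    if (is.null(dim)) dim <- max(est_x$dim, est_y$dim)
  }
  ex <- embed_series(x, dim, delay)
  ey <- embed_series(y, dim, delay)
  if (is.null(params$radius)) {
    tuned <- tune_radius(ex, ey, target_rr = params$target_rr)
    radius <- tuned$radius
  } else {
    radius <- params$radius
  }
  st <- crqa_stats(ex, ey, radius, params$min_line)
  list(rec_pct = st$rec_pct, maxline = st$maxline, radius_used = radius,
       delay = delay, dim = dim)
}
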