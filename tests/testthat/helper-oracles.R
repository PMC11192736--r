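# Brute-force reference implementations, kept deliberately naive and
# independent of the package's computation paths.

# Equal-width binning identical in definition to the package's rule:
# ceiling(sqrt(n)) bins capped at 64, over the range of the full series.
oracle_bin <- function(v, rng, nb) {
  brk <- seq(rng[1], rng[2], length.out = nb + 1)
  as.integer(cut(v, brk, right = FALSE, include.lowest = TRUE))
}

# Mutual information (bits) between x(t) and x(t + tau), nested-loop sum
# over the joint histogram.
oracle_ami <- function(x, tau) {
  n <- length(x) - tau
  nb <- min(ceiling(sqrt(n)), 64)
  rng <- range(x)
  a <- oracle_bin(x[1:n], rng, nb)
  b <- oracle_bin(x[(1 + tau):(n + tau)], rng, nb)
  mi <- 0
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      pij <- sum(a == i & b == j) / n
      if (pij > 0) {
        mi <- mi + pij * log2(pij / ((sum(a == i) / n) * (sum(b == j) / n)))
      }
    }
  }
  mi
}

oracle_ami_curve <- function(x, max_lag) {
  vapply(0:max_lag, function(tau) oracle_ami(x, tau), numeric(1))
}

# Kennel FNN fractions, plain loops.
oracle_fnn <- function(x, delay, max_dim, rtol = 15, atol = 2) {
  N <- length(x)
  sdx <- stats::sd(x)
  out <- rep(NA_real_, max_dim)
  for (d in seq_len(max_dim)) {
    n <- N - d * delay
    if (n < 2) break
    nfalse <- 0
    for (i in seq_len(n)) {
      dist2 <- rep(Inf, n)
      for (j in seq_len(n)) {
        if (j == i) next
        s <- 0
        for (k in 0:(d - 1)) s <- s + (x[i + k * delay] - x[j + k * delay])^2
        dist2[j] <- s
      }
      j <- which.min(dist2)
      rd <- sqrt(dist2[j])
      extra <- x[i + d * delay] - x[j + d * delay]
      rd1 <- sqrt(dist2[j] + extra^2)
      false_nb <- if (rd == 0) abs(extra) > 0 else
        (abs(extra) / rd > rtol) || (rd1 > atol * sdx)
      if (false_nb) nfalse <- nfalse + 1
    }
    out[d] <- nfalse / n
  }
  out
}

oracle_embed <- function(x, dim, delay) {
  n <- length(x) - (dim - 1) * delay
  t(vapply(seq_len(n),
           function(i) x[i + (0:(dim - 1)) * delay], numeric(dim)))
}

# Dense 0/1 cross-recurrence matrix from explicit distances.
oracle_rec_matrix <- function(ex, ey, radius) {
  nx <- nrow(ex); ny <- nrow(ey)
  R <- matrix(0L, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      R[i, j] <- as.integer(sqrt(sum((ex[i, ] - ey[j, ])^2)) <= radius)
    }
  }
  R
}

oracle_rec_rate <- function(R) 100 * sum(R) / length(R)

# Longest diagonal run, scanning every diagonal with an explicit counter.
oracle_maxline <- function(R, min_line = 2) {
  nx <- nrow(R); ny <- ncol(R)
  best <- 0
  for (i0 in seq_len(nx)) {
    for (j0 in seq_len(ny)) {
      if (i0 > 1 && j0 > 1) next  # only diagonal starts
      i <- i0; j <- j0; run <- 0
      while (i <= nx && j <= ny) {
        if (R[i, j] == 1) {
          run <- run + 1
          if (run > best) best <- run
        } else {
          run <- 0
        }
        i <- i + 1; j <- j + 1
      }
    }
  }
  if (best < min_line) 0 else best
}
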