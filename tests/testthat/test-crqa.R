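test_that("AMI at lag zero is the histogram entropy and the curve maximum", {
  set.seed(10)
  x <- stats::rnorm(400)
  ami <- average_mutual_information(x, 20)
  nb <- min(ceiling(sqrt(400)), 64)
  p <- tabulate(oracle_bin(x, range(x), nb), nb) / 400
  H <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(ami[1], H, tolerance = 1e-12)
  expect_equal(which.max(ami), 1L)
})

test_that("AMI of a shuffled series is near zero at positive lags", {
  set.seed(11)
  x <- sample(stats::rnorm(600))
  ami <- average_mutual_information(x, 10)
  # null scale: AMI of independent pairs at this n and bin count
  null <- replicate(20, oracle_ami(sample(x), 5))
  expect_true(all(ami[-1] < mean(null) + 3 * stats::sd(null)))
})

test_that("the sinusoid delay choice tracks the brute-force AMI oracle", {
  tr <- sine_trace(freq = 1.4, dur = 30, fs = 50)
  ami <- average_mutual_information(tr$x, 30)
  d <- select_delay(ami)
  expect_identical(d, select_delay(oracle_ami_curve(tr$x, 30)))
  # a useful embedding delay: at most quarter-period-plus-slack, never 0
  expect_gte(d, 1)
  expect_lte(d, ceiling(50 / (4 * 1.4)) + 2)
})

test_that("AMI rejects constant input", {
  expect_error(average_mutual_information(rep(1, 100), 10), "degenerate")
})

test_that("delay selection picks the first local minimum with fallback", {
  expect_equal(select_delay(c(3, 1, 2, 0.5)), 1)
  v <- c(5, 4, 3, 2, 1, 0.5)  # strictly decreasing
  expect_warning(d <- select_delay(v), "global minimum")
  expect_equal(d, 5)
  vshape <- c(30:1, 0.5, 1:10)   # minimum at lag 31... construct at 24
  curve24 <- c(seq(10, 1, length.out = 25), seq(1.2, 3, length.out = 6))
  expect_equal(select_delay(curve24), 24)
})

test_that("FNN separates deterministic signals from noise", {
  tr <- sine_trace(freq = 1.4, dur = 10, fs = 50)
  fnn <- false_nearest_neighbours(tr$x, delay = 9, max_dim = 4)
  expect_lt(fnn[2], 0.01)
  set.seed(12)
  noise <- stats::rnorm(400)
  fnn_n <- false_nearest_neighbours(noise, delay = 1, max_dim = 5)
  expect_true(all(fnn_n[1:5] > 0.1))
  one <- false_nearest_neighbours(noise, delay = 1, max_dim = 1)
  expect_length(one, 1)
})

test_that("embedding-dimension selection follows first-minimum-then-threshold", {
  expect_equal(select_embedding_dim(c(0.8, 0.02, 0.03)), 2)
  expect_equal(select_embedding_dim(c(0.8, 0.4, 0.2, 0.009, 0.004, 0.001)), 4)
  curve7 <- c(0.9, 0.7, 0.5, 0.3, 0.2, 0.15, 0.12, 0.13, 0.14, 0.2)
  expect_equal(select_embedding_dim(curve7), 7)
})

test_that("delay embedding has the documented geometry", {
  x <- stats::rnorm(10)
  e1 <- embed_series(x, 1, 3)
  expect_equal(dim(e1), c(10, 1))
  expect_equal(e1[, 1], x)
  e3 <- embed_series(1:10, 3, 2)
  expect_equal(nrow(e3), 6)
  expect_equal(e3[1, ], c(1, 3, 5))
  expect_equal(nrow(embed_series(stats::rnorm(4200), 7, 24)), 4056)
  expect_error(embed_series(1:5, 3, 3), "too short")
})

test_that("the 3x3 hand-worked cross-recurrence example is exact", {
  ex <- matrix(c(0, 1, 2), ncol = 1)
  ey <- matrix(c(0, 2, 4), ncol = 1)
  R <- cross_recurrence_matrix(ex, ey, 1)
  expect_equal(R, rbind(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L)))
  expect_equal(recurrence_rate(R), 400 / 9)
  expect_error(cross_recurrence_matrix(ex, matrix(0, 2, 2), 1), "alignment")
})

test_that("recurrence rate saturates at the extremes", {
  set.seed(13)
  ex <- embed_series(stats::rnorm(50), 2, 1)
  ey <- embed_series(stats::rnorm(50), 2, 1)
  big <- cpp_max_dist_for_test(ex, ey) + 1
  expect_equal(recurrence_rate(cross_recurrence_matrix(ex, ey, big)), 100)
  expect_equal(recurrence_rate(cross_recurrence_matrix(ex, ey, 1e-9)), 0)
  expect_error(recurrence_rate(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("maxline counts the longest diagonal run above min_line", {
  R <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 1L))
  expect_equal(max_line(R), 3L)
  expect_equal(max_line(matrix(0L, 4, 4)), 0L)
  # a lone diagonal pair below min_line counts as zero
  R2 <- diag(2)
  expect_equal(max_line(R2, min_line = 3), 0L)
  expect_equal(max_line(R2, min_line = 2), 2L)
  # identical embedded series: the main diagonal runs the full length
  x <- embed_series(sin(seq(0, 10, length.out = 80)), 2, 3)
  Rid <- cross_recurrence_matrix(x, x, 0.05)
  expect_equal(max_line(Rid), nrow(x))
})

test_that("swapping the inputs transposes the matrix and keeps maxline", {
  set.seed(14)
  ex <- embed_series(stats::rnorm(60), 2, 2)
  ey <- embed_series(stats::rnorm(70), 2, 2)
  Rxy <- cross_recurrence_matrix(ex, ey, 1.5)
  Ryx <- cross_recurrence_matrix(ey, ex, 1.5)
  expect_equal(Rxy, t(Ryx))
  expect_equal(max_line(Rxy), max_line(Ryx))
  st_xy <- crqa_stats(ex, ey, 1.5)
  st_yx <- crqa_stats(ey, ex, 1.5)
  expect_equal(st_xy$maxline, st_yx$maxline)
  expect_equal(st_xy$rec_pct, st_yx$rec_pct)
})

test_that("recurrence rate is non-decreasing in the radius", {
  set.seed(15)
  ex <- embed_series(stats::rnorm(80), 3, 2)
  ey <- embed_series(stats::rnorm(80), 3, 2)
  radii <- seq(0.1, 4, length.out = 15)
  rr <- vapply(radii, function(r) crqa_stats(ex, ey, r)$rec_pct, numeric(1))
  expect_true(all(diff(rr) >= 0))
})

test_that("radius tuning reaches the target recurrence rate", {
  set.seed(16)
  pair <- preprocess_trial(simulate_short_pair(2, seed = 21), short_pre())
  x <- as.numeric(scale(pair$participant$x))
  y <- as.numeric(scale(pair$avatar$x))
  ex <- embed_series(x, 5, 9)
  ey <- embed_series(y, 5, 9)
  tuned <- tune_radius(ex, ey, target_rr = 5, tol = 0.5)
  expect_gte(tuned$rec_pct, 4.5)
  expect_lte(tuned$rec_pct, 5.5)
  # target 100% is met exactly at the maximum pairwise distance
  sat <- tune_radius(ex[1:50, ], ey[1:50, ], target_rr = 100, tol = 0.5)
  expect_equal(sat$rec_pct, 100)
  # coincident points make tiny targets unattainable
  same <- matrix(rep(c(0, 1), each = 5), ncol = 1)
  expect_error(tune_radius(same, same, target_rr = 0.0001, tol = 0.00005),
               "tuning error")
})

test_that("streamed statistics match the dense-matrix path", {
  set.seed(17)
  for (case in 1:10) {
    n <- sample(30:90, 1)
    ex <- embed_series(stats::rnorm(n), 2, 2)
    ey <- embed_series(stats::rnorm(n), 2, 2)
    r <- stats::runif(1, 0.3, 2)
    R <- cross_recurrence_matrix(ex, ey, r)
    st <- crqa_stats(ex, ey, r)
    expect_equal(st$rec_pct, recurrence_rate(R), tolerance = 1e-12)
    expect_equal(st$maxline, max_line(R))
  }
})

test_that("%REC and MaxLine at fixed radius grow with coupling", {
  ks <- c(0, 1, 4)
  pre <- short_pre()
  res <- vapply(ks, function(K) {
    m <- vapply(1:8, function(s) {
      pair <- preprocess_trial(simulate_short_pair(K, seed = 77 * s + K), pre)
      ex <- embed_series(as.numeric(scale(pair$participant$x)), 5, 9)
      ey <- embed_series(as.numeric(scale(pair$avatar$x)), 5, 9)
      st <- crqa_stats(ex, ey, radius = 1)
      c(st$rec_pct, st$maxline)
    }, numeric(2))
    rowMeans(m)
  }, numeric(2))
  expect_gt(stats::cor(ks, res[1, ], method = "spearman"), 0)
  expect_gt(stats::cor(ks, res[2, ], method = "spearman"), 0)
})
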