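test_that("covariate generation matches the questionnaire calibration", {
  cfg <- sim_config()
  cv <- generate_covariates(10000, cfg, seed = 101)
  expect_lt(abs(mean(cv$lsas) - 55.43), 1)
  expect_lt(abs(mean(cv$aq) - 9.99), 0.3)
  expect_lt(abs(stats::sd(cv$lsas) - 23.52), 1)
  expect_lt(abs(stats::sd(cv$aq) - 4.83), 0.3)
  expect_true(all(cv$lsas >= 9 & cv$lsas <= 119))
  expect_true(all(cv$aq >= 1 & cv$aq <= 25))
  # balanced assignment, determinism
  two <- generate_covariates(2, cfg, seed = 5)
  expect_setequal(two$gaze_condition, c("direct", "averted"))
  expect_identical(generate_covariates(50, cfg, seed = 7),
                   generate_covariates(50, cfg, seed = 7))
  bad <- sim_config(lsas_mean = 200)
  expect_error(generate_covariates(10, bad, seed = 1), "config error")
})

test_that("the avatar oscillates at the metronome rate", {
  cfg <- sim_config()
  av <- simulate_avatar(cfg, seed = 44)
  expect_length(av$x, 4500)
  expect_equal(trace_duration_for_test(av), 90)
  sp <- Mod(stats::fft(av$x - mean(av$x)))[1:2250]
  f <- (0:2249) / 90
  peak <- f[which.max(sp)]
  expect_lt(abs(peak - 84 / 60), 1 / 90 + 1e-9)  # within one FFT bin
  # no seed: deterministic pure sinusoid, phase 0
  pure <- simulate_avatar(cfg)
  expect_equal(pure$x, sin(2 * pi * 1.4 * pure$t), tolerance = 1e-9)
})

test_that("the coupled follower locks for strong coupling, wanders for none", {
  cfg <- sim_config()
  rho_k0 <- mean(vapply(1:50, function(s) {
    av <- simulate_avatar(cfg, seed = 3000 + s)
    pp <- simulate_participant(av, 0, cfg, seed = 4000 + s)
    Mod(mean(exp(1i * (attr(pp, "phase") - attr(av, "phase")))))
  }, numeric(1)))
  expect_lt(rho_k0, 0.3)
  quiet <- sim_config(process_noise_sd = 0.1)
  rho_k5 <- mean(vapply(1:10, function(s) {
    av <- simulate_avatar(quiet, seed = 3000 + s)
    pp <- simulate_participant(av, 5, quiet, seed = 4000 + s)
    Mod(mean(exp(1i * (attr(pp, "phase") - attr(av, "phase")))))
  }, numeric(1)))
  expect_gt(rho_k5, 0.9)
  a <- simulate_participant(simulate_avatar(cfg, seed = 9), 2, cfg, seed = 10)
  b <- simulate_participant(simulate_avatar(cfg, seed = 9), 2, cfg, seed = 10)
  expect_identical(a$x, b$x)
})

test_that("condition coupling reproduces the direct-vs-averted ordering", {
  cfg <- short_cfg()
  row_of <- function(gc) data.frame(participant_id = "p", gaze_condition = gc,
                                    lsas = 55, aq = 10)
  rhos <- vapply(1:100, function(s) {
    d <- simulate_dyad_trial(row_of("direct"), "spontaneous", cfg,
                             seed = 5000 + 2 * s)
    a <- simulate_dyad_trial(row_of("averted"), "spontaneous", cfg,
                             seed = 5001 + 2 * s)
    c(truth_rho(d$pair), truth_rho(a$pair))
  }, numeric(2))
  expect_gt(mean(rhos[1, ]), mean(rhos[2, ]))
})

test_that("coupling strength composes condition and covariate effects", {
  cfg <- sim_config()
  row <- data.frame(participant_id = "p", gaze_condition = "averted",
                    lsas = cfg$lsas_mean, aq = cfg$aq_mean)
  expect_equal(coupling_strength(row, "spontaneous", cfg)$K, cfg$K0)
  expect_equal(coupling_strength(row, "intentional", cfg)$K,
               cfg$K0 + cfg$dK_intentional)
  null_cfg <- sim_config(dK_intentional = 0, dK_direct = 0,
                         b_lsas_averted = 0, b_lsas_direct = 0, b_aq = 0)
  row2 <- row; row2$gaze_condition <- "direct"; row2$lsas <- 100
  expect_equal(coupling_strength(row2, "intentional", null_cfg)$K,
               null_cfg$K0)
  floor_cfg <- sim_config(K0 = 0.1, b_aq = -0.2)
  row3 <- row; row3$aq <- 25
  ks <- coupling_strength(row3, "spontaneous", floor_cfg)
  expect_equal(ks$K, 0)
  expect_true(ks$floored)
  tr <- simulate_dyad_trial(row3, "spontaneous", short_cfg(K0 = 0.1, b_aq = -0.2),
                            seed = 1)
  expect_true(tr$truth$floored)
})

test_that("gaze simulation hits its stationary probability and AQ gradient", {
  flat <- sim_config(gaze_base = 0, gaze_shift_direct = 0,
                     gaze_shift_intentional = 0, gaze_slope_aq = 0)
  row <- data.frame(participant_id = "p", gaze_condition = "direct",
                    lsas = 55, aq = 10)
  props <- vapply(1:20, function(s) {
    gaze_proportion(simulate_gaze(row, "spontaneous", flat, seed = 7000 + s))
  }, numeric(1))
  expect_lt(abs(mean(props) - 0.5), 0.05)
  steep <- sim_config(gaze_slope_aq = -0.3)
  cv <- generate_covariates(200, steep, seed = 71)
  pr <- vapply(1:200, function(i) {
    gaze_proportion(simulate_gaze(cv[i, ], "spontaneous", steep,
                                  seed = 7300 + i))
  }, numeric(1))
  expect_lt(stats::cor(cv$aq, pr, method = "spearman"), 0)
  g1 <- simulate_gaze(row, "spontaneous", flat, seed = 3)
  g2 <- simulate_gaze(row, "spontaneous", flat, seed = 3)
  expect_identical(g1$aoi, g2$aoi)
})

test_that("generate_study writes a complete, regenerable study", {
  cfg <- short_cfg(n_participants = 4, seed = 123)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  generate_study(cfg, dir1)
  files <- list.files(dir1)
  expect_length(grep("_movement\\.csv$", files), 8)
  expect_length(grep("_gaze\\.csv$", files), 8)
  expect_true(all(c("covariates.csv", "truth.csv", "manifest.txt") %in% files))
  truth <- utils::read.csv(file.path(dir1, "truth.csv"))
  expect_equal(nrow(truth), 8)
  generate_study(cfg, dir2)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})
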