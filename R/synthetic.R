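#' Synthetic-study configuration
#'
#' Defaults encode the study conditions the pipeline expects: two trials per
#' participant (spontaneous then intentional), two between-participant
#' avatar-gaze conditions, 90 s trials sampled at 50 Hz, arm curls paced at
#' an 84 bpm metronome (1.4 Hz), and questionnaire covariates matched to the
#' published sample moments (LSAS M 55.43, SD 23.52, range 9-119; AQ M 9.99,
#' SD 4.83, range 1-25).
#'
#' The movement generator is a stochastic two-oscillator phase model: the
#' avatar is a (slightly jittered) metronome-paced oscillator and the
#' participant a Kuramoto-coupled follower whose coupling strength K carries
#' the condition and covariate effects.
#'
#' @param n_participants Number of participants (default 134).
#' @param fs Sample rate, Hz.
#' @param trial_s Trial duration, seconds.
#' @param metronome_bpm Metronome rate, beats per minute.
#' @param amplitude Movement amplitude, arbitrary units.
#' @param process_noise_sd Phase diffusion SD, rad/sqrt(s).
#' @param meas_noise_sd Additive displacement noise SD.
#' @param detuning_sd SD of the participant's natural-frequency offset, Hz.
#' @param freq_jitter Fractional slow frequency jitter of the avatar (< 0.02).
#' @param K0 Baseline coupling, rad/s (spontaneous, averted, mean covariates).
#' @param dK_intentional Coupling increment for intentional trials, rad/s.
#' @param dK_direct Coupling increment under direct avatar gaze, rad/s.
#' @param b_lsas_averted,b_lsas_direct LSAS slope on K (rad/s per centred
#'   point) under averted / direct gaze.
#' @param b_aq AQ slope on K, rad/s per centred point.
#' @param lsas_mean,lsas_sd,lsas_range LSAS calibration targets.
#' @param aq_mean,aq_sd,aq_range AQ calibration targets.
#' @param gaze_base Logit of the stationary avatar-gaze probability in the
#'   averted-gaze spontaneous cell at mean AQ.
#' @param gaze_shift_direct,gaze_shift_intentional Logit shifts.
#' @param gaze_slope_aq Logit slope per centred AQ point.
#' @param gaze_switch Per-sample switching intensity of the two-state gaze
#'   chain (geometric dwell times; smaller = longer dwells).
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 134, fs = 50, trial_s = 90,
                       metronome_bpm = 84, amplitude = 1,
                       process_noise_sd = 0.7, meas_noise_sd = 0.05,
                       detuning_sd = 0.05, freq_jitter = 0.01,
                       K0 = 0.6, dK_intentional = 3, dK_direct = 0.4,
                       b_lsas_averted = 0.008, b_lsas_direct = -0.002,
                       b_aq = -0.01,
                       lsas_mean = 55.43, lsas_sd = 23.52,
                       lsas_range = c(9, 119),
                       aq_mean = 9.99, aq_sd = 4.83, aq_range = c(1, 25),
                       gaze_base = 0.5, gaze_shift_direct = 0.5,
                       gaze_shift_intentional = 0.5, gaze_slope_aq = -0.06,
                       gaze_switch = 0.04,
                       seed = 1L) {
  stopifnot(n_participants >= 2, fs > 0, trial_s > 0, metronome_bpm > 0,
            process_noise_sd >= 0, meas_noise_sd >= 0, detuning_sd >= 0,
            freq_jitter >= 0, freq_jitter < 0.02,
            lsas_range[1] < lsas_range[2], aq_range[1] < aq_range[2],
            gaze_switch > 0, gaze_switch <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Parent (mu, sigma) of a truncated normal whose *truncated* mean and SD
# equal the targets; solved numerically so the generator matches the printed
# sample moments in expectation.
truncnorm_solve <- function(mean, sd, lo, hi) {
  moments <- function(mu, sigma) {
    a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
    Z <- stats::pnorm(b) - stats::pnorm(a)
    d <- (stats::dnorm(a) - stats::dnorm(b)) / Z
    m <- mu + sigma * d
    v <- sigma^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / Z - d^2)
    c(m, sqrt(v))
  }
  obj <- function(par) {
    mo <- moments(par[1], exp(par[2]))
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm <- function(n, mu, sigma, lo, hi) {
  plo <- stats::pnorm(lo, mu, sigma)
  phi <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(stats::runif(n, plo, phi), mu, sigma)
}

#' Generate the per-participant covariate table
#'
#' LSAS and AQ are drawn from truncated normals whose parent parameters are
#' solved so the truncated moments equal the configured targets; scores are
#' rounded to whole questionnaire points. Gaze condition is assigned by
#' balanced randomisation.
#'
#' @param n Number of participants.
#' @param config A [sim_config].
#' @param seed Random seed (default: the config's master seed).
#' @return Data.frame `participant_id, gaze_condition, lsas, aq`.
#' @export
generate_covariates <- function(n = NULL, config = sim_config(),
                                seed = config$seed) {
  if (is.null(n)) n <- config$n_participants
  stopifnot(n >= 2)
  if (config$lsas_mean < config$lsas_range[1] ||
      config$lsas_mean > config$lsas_range[2] ||
      config$aq_mean < config$aq_range[1] ||
      config$aq_mean > config$aq_range[2]) {
    stop("config error: covariate mean outside its bounds", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pl <- truncnorm_solve(config$lsas_mean, config$lsas_sd,
                        config$lsas_range[1], config$lsas_range[2])
  pa <- truncnorm_solve(config$aq_mean, config$aq_sd,
                        config$aq_range[1], config$aq_range[2])
  lsas <- round(rtruncnorm(n, pl$mu, pl$sigma,
                           config$lsas_range[1], config$lsas_range[2]))
  aq <- round(rtruncnorm(n, pa$mu, pa$sigma,
                         config$aq_range[1], config$aq_range[2]))
  cond <- sample(rep(c("direct", "averted"), c(ceiling(n / 2), floor(n / 2))))
  data.frame(participant_id = sprintf("p%03d", seq_len(n)),
             gaze_condition = cond, lsas = lsas, aq = aq,
             stringsAsFactors = FALSE)
}

#' Simulate the avatar's movement trace
#'
#' A metronome-paced sinusoid `A * sin(theta(t))` whose instantaneous
#' frequency carries a small smooth jitter (two slow random-phase drift
#' components, fractional amplitude `freq_jitter`), emulating a pre-recorded
#' human mover keeping time at the metronome rate.
#'
#' @param config A [sim_config].
#' @param seed Random seed (NULL for a deterministic pure sinusoid phase 0).
#' @param trial_s Override of the trial duration.
#' @return A [movement_trace] with the realised phase in attribute `phase`.
#' @export
simulate_avatar <- function(config = sim_config(), seed = NULL,
                            trial_s = config$trial_s) {
  f0 <- config$metronome_bpm / 60
  dt <- 1 / config$fs
  t <- seq(0, trial_s - dt, by = dt)
  if (!is.null(seed)) set.seed(seed)
  if (config$freq_jitter > 0 && !is.null(seed)) {
    ph <- stats::runif(2, 0, 2 * pi)
    drift <- config$freq_jitter / sqrt(2) *
      (sin(2 * pi * 0.03 * t + ph[1]) + sin(2 * pi * 0.07 * t + ph[2]))
    phi0 <- stats::runif(1, 0, 2 * pi)
  } else {
    drift <- rep(0, length(t))
    phi0 <- 0
  }
  freq <- f0 * (1 + drift)
  theta <- phi0 + 2 * pi * dt * (cumsum(freq) - freq[1])
  x <- config$amplitude * sin(theta)
  out <- movement_trace(t, x, fs = config$fs, actor = "avatar")
  attr(out, "phase") <- theta
  out
}

#' Simulate the participant's coupled movement trace
#'
#' Euler-Maruyama integration of the stochastic Kuramoto follower
#' `d(theta_p) = (omega_p + K * sin(theta_a - theta_p)) dt + sigma_eta dW`,
#' where `omega_p` is the metronome frequency plus a participant-specific
#' detuning. Displacement is `A * sin(theta_p)` plus measurement noise.
#'
#' @param avatar Avatar [movement_trace] from [simulate_avatar].
#' @param K Coupling strength, rad/s (>= 0).
#' @param config A [sim_config].
#' @param seed Random seed.
#' @param detuning_hz Natural-frequency offset; `NULL` draws it from
#'   `N(0, detuning_sd)`.
#' @return A [movement_trace] with attributes `phase` and `detuning_hz`.
#' @export
simulate_participant <- function(avatar, K, config = sim_config(),
                                 seed = NULL, detuning_hz = NULL) {
  stopifnot(inherits(avatar, "movement_trace"), K >= 0)
  theta_a <- attr(avatar, "phase")
  if (is.null(theta_a)) {
    theta_a <- Arg(analytic_signal(avatar$x - mean(avatar$x)))
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(detuning_hz)) detuning_hz <- stats::rnorm(1, 0, config$detuning_sd)
  n <- length(avatar$x)
  dt <- 1 / avatar$fs
  omega <- 2 * pi * (config$metronome_bpm / 60 + detuning_hz)
  noise <- stats::rnorm(n, 0, config$process_noise_sd * sqrt(dt))
  theta <- numeric(n)
  theta[1] <- theta_a[1] + stats::runif(1, -pi, pi)
  for (i in 2:n) {
    dth <- (omega + K * sin(theta_a[i - 1] - theta[i - 1])) * dt + noise[i]
    if (abs(dth) > pi) {
      stop("integration error: phase step exceeded pi; reduce noise or K",
           call. = FALSE)
    }
    theta[i] <- theta[i - 1] + dth
  }
  x <- config$amplitude * sin(theta) +
    stats::rnorm(n, 0, config$meas_noise_sd)
  out <- movement_trace(avatar$t, x, fs = avatar$fs, actor = "participant")
  attr(out, "phase") <- theta
  attr(out, "detuning_hz") <- detuning_hz
  out
}

#' Coupling strength for a participant and trial type
#'
#' `K = K0 + dK_intentional * [intentional] + dK_direct * [direct]
#'     + b_lsas_averted * lsas_c * [averted]
#'     + b_lsas_direct * lsas_c * [direct] + b_aq * aq_c`, floored at 0.
#' Covariates are centred at the configured population means.
#'
#' @param row One covariate-table row.
#' @param trial_type `"spontaneous"` or `"intentional"`.
#' @param config A [sim_config].
#' @return List with `K` and `floored` (whether the floor engaged).
#' @export
coupling_strength <- function(row, trial_type, config = sim_config()) {
  lsas_c <- row$lsas - config$lsas_mean
  aq_c <- row$aq - config$aq_mean
  direct <- row$gaze_condition == "direct"
  K <- config$K0 +
    config$dK_intentional * (trial_type == "intentional") +
    config$dK_direct * direct +
    config$b_lsas_averted * lsas_c * (!direct) +
    config$b_lsas_direct * lsas_c * direct +
    config$b_aq * aq_c
  list(K = max(K, 0), floored = K < 0)
}

#' Simulate one dyad trial
#'
#' Composes [simulate_avatar] and [simulate_participant] with the coupling
#' implied by the participant's condition and covariates.
#'
#' @param participant_row One row of the covariate table.
#' @param trial_type `"spontaneous"` or `"intentional"`.
#' @param config A [sim_config].
#' @param seed Random seed for the trial.
#' @return List with `pair` (a [trial_pair]) and `truth` (realised K,
#'   detuning, floor flag, seed).
#' @export
simulate_dyad_trial <- function(participant_row,
                                trial_type = c("spontaneous", "intentional"),
                                config = sim_config(), seed = NULL) {
  trial_type <- match.arg(trial_type)
  ks <- coupling_strength(participant_row, trial_type, config)
  avatar <- simulate_avatar(config, seed = seed)
  participant <- simulate_participant(avatar, ks$K, config,
                                      seed = if (is.null(seed)) NULL else seed + 1L)
  pair <- trial_pair(participant, avatar,
                     gaze_condition = participant_row$gaze_condition,
                     coordination = trial_type)
  truth <- data.frame(participant_id = participant_row$participant_id,
                      coordination = trial_type,
                      K = ks$K, floored = ks$floored,
                      detuning_hz = attr(participant, "detuning_hz"),
                      seed = if (is.null(seed)) NA_integer_ else seed)
  list(pair = pair, truth = truth)
}

#' Simulate a gaze AOI series
#'
#' Two-state Markov chain (avatar / room) whose stationary avatar
#' probability is `plogis(base + shift_direct * [direct] +
#' shift_intentional * [intentional] + slope_aq * aq_c)`; dwell times are
#' geometric with switching intensity `gaze_switch`.
#'
#' @inheritParams simulate_dyad_trial
#' @return An `aoi_series` spanning the trial at the movement sample rate.
#' @export
simulate_gaze <- function(participant_row,
                          trial_type = c("spontaneous", "intentional"),
                          config = sim_config(), seed = NULL) {
  trial_type <- match.arg(trial_type)
  if (!is.null(seed)) set.seed(seed)
  aq_c <- participant_row$aq - config$aq_mean
  p <- stats::plogis(config$gaze_base +
                     config$gaze_shift_direct *
                       (participant_row$gaze_condition == "direct") +
                     config$gaze_shift_intentional *
                       (trial_type == "intentional") +
                     config$gaze_slope_aq * aq_c)
  s <- config$gaze_switch
  n <- round(config$trial_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  state <- integer(n)               # 1 = avatar, 0 = room
  state[1] <- stats::rbinom(1, 1, p)
  u <- stats::runif(n)
  for (i in 2:n) {
    # transition probabilities chosen so the stationary probability is p
    pr <- if (state[i - 1] == 1) 1 - s * (1 - p) else s * p
    state[i] <- as.integer(u[i] < pr)
  }
  aoi_series(t, state)
}

#' Generate a complete synthetic study on disk
#'
#' Writes, per participant and trial, a combined movement CSV
#' (`t,participant,avatar`) and a gaze AOI CSV, plus `covariates.csv`, the
#' truth table (realised coupling per trial) and a flat key=value manifest
#' with all seeds. Trial order is fixed: spontaneous first, then
#' intentional.
#'
#' @param config A [sim_config].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a named list.
#' @export
generate_study <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cov <- generate_covariates(config$n_participants, config, seed = config$seed)
  utils::write.csv(cov, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- NULL
  manifest <- list(seed = config$seed, n_participants = config$n_participants,
                   fs = config$fs, trial_s = config$trial_s,
                   metronome_bpm = config$metronome_bpm)
  for (i in seq_len(nrow(cov))) {
    for (j in 1:2) {
      trial_type <- c("spontaneous", "intentional")[j]
      tseed <- (config$seed + 7919L * i + 104729L * j) %% 2000000000L
      sim <- simulate_dyad_trial(cov[i, ], trial_type, config, seed = tseed)
      stem <- sprintf("%s_%s", cov$participant_id[i], trial_type)
      write_pair_csv(sim$pair, file.path(out_dir, paste0(stem, "_movement.csv")))
      gz <- simulate_gaze(cov[i, ], trial_type, config, seed = tseed + 2L)
      utils::write.csv(
        data.frame(t = gz$t, aoi = as.character(gz$aoi)),
        file.path(out_dir, paste0(stem, "_gaze.csv")),
        row.names = FALSE, quote = FALSE)
      truth <- rbind(truth, sim$truth)
      manifest[[paste0("seed_", stem)]] <- tseed
    }
  }
  utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(paste0(names(manifest), "=", unlist(manifest)),
             file.path(out_dir, "manifest.txt"))
  invisible(manifest)
}

#' Simulate a study table directly from the inference model's own
#' generative form
#'
#' For calibration of the mixed-model stage without the signal pipeline:
#' outcomes are drawn from
#' `y = b0 + b_coord * coord + b_gaze * gaze + b_cg * coord * gaze +
#'  b_q * q_c + (interaction terms) + u_participant + e`,
#' with a by-participant random intercept `u ~ N(0, sd_u^2)` and residual
#' `e ~ N(0, sd_e^2)`.
#'
#' @param n Number of participants (two rows each).
#' @param coefs Named list of true coefficients; see Defaults in the source.
#' @param config A [sim_config] (for the covariate generator).
#' @param seed Random seed.
#' @return Data.frame with `participant_id`, factor codes `coordination`
#'   (0/1), `gaze` (0/1), centred covariates, and outcome `y`.
#' @export
simulate_study_table <- function(n = 134,
                                 coefs = list(),
                                 config = sim_config(),
                                 seed = 1L) {
  co <- utils::modifyList(
    list(b0 = 0.9, b_coord = 0.5, b_gaze = -0.15, b_cg = 0.15,
         b_lsas = 0, b_lsas_gaze = 0, sd_u = 0.2, sd_e = 0.25),
    coefs)
  cov <- generate_covariates(n, config, seed = seed)
  set.seed(seed + 1L)
  u <- stats::rnorm(n, 0, co$sd_u)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(participant_id = cov$participant_id[i],
               coordination = c(0, 1),
               gaze = as.integer(cov$gaze_condition[i] == "averted"),
               lsas = cov$lsas[i], aq = cov$aq[i])
  }))
  rows$lsas_c <- rows$lsas - mean(cov$lsas)
  rows$aq_c <- rows$aq - mean(cov$aq)
  rows$y <- with(rows,
    co$b0 + co$b_coord * coordination + co$b_gaze * gaze +
      co$b_cg * coordination * gaze + co$b_lsas * lsas_c +
      co$b_lsas_gaze * lsas_c * gaze) +
    u[match(rows$participant_id, cov$participant_id)] +
    stats::rnorm(nrow(rows), 0, co$sd_e)
  rows
}
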