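# Shared fixtures built in code.

# A uniform trace of an arbitrary signal function of time.
make_trace <- function(f, dur = 90, fs = 50, actor = "participant") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  movement_trace(t, f(t), fs = fs, actor = actor)
}

sine_trace <- function(freq = 1.4, dur = 90, fs = 50, amp = 1, phase = 0,
                       actor = "participant") {
  make_trace(function(t) amp * sin(2 * pi * freq * t + phase),
             dur = dur, fs = fs, actor = actor)
}

# A short, fast simulated dyad for pipeline-level tests: shortened trials
# with preprocessing scaled to match (trim 6 s, standardise to 24 s).
short_cfg <- function(...) sim_config(trial_s = 30, ...)
short_pre <- function() preprocess_config(trim_s = 6, target_s = 24)

simulate_short_pair <- function(K, seed, cfg = short_cfg()) {
  av <- simulate_avatar(cfg, seed = seed)
  pp <- simulate_participant(av, K, cfg, seed = seed + 1L)
  trial_pair(pp, av, "direct", "spontaneous")
}

# rho computed straight from the generator's own phases (no Hilbert step),
# for generator-level checks.
truth_rho <- function(pair) {
  dphi <- attr(pair$participant, "phase") - attr(pair$avatar, "phase")
  Mod(mean(exp(1i * dphi)))
}

trace_duration_for_test <- function(trace) length(trace$x) / trace$fs

# phase unwrap via wrapped first differences
unwrap_for_test <- function(p) {
  d <- Arg(exp(1i * diff(p)))
  cumsum(c(p[1], d))
}

cpp_max_dist_for_test <- function(ex, ey) {
  m <- 0
  for (i in seq_len(nrow(ex))) {
    m <- max(m, sqrt(colSums((t(ey) - ex[i, ])^2)))
  }
  m
}

build_codes_table_for_test <- function(tab) {
  tab$coordination_c <- tab$coordination - mean(tab$coordination)
  tab$gaze_c <- tab$gaze - mean(tab$gaze)
  tab
}
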