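# dyadsync

Coordination dynamics of dyadic rhythmic movement: from paired displacement
time series to phase, spectral and cross-recurrence coordination indices,
through mixed-effects models of condition and symptom effects.

The package targets studies of interpersonal coordination in which a
participant performs paced rhythmic movement (arm curls at an 84 bpm
metronome, recorded at 50 Hz for 90 s per trial) opposite a partner — for
example a virtual avatar whose gaze is experimentally directed at or away
from the participant — with spontaneous and intentional coordination
trials, gaze area-of-interest recordings, and continuous symptom measures
(LSAS, AQ) as covariates. It is written for researchers in movement
science, computational behavioral science and psychopathology who want the
full reduction-and-inference chain as tested, scriptable functions.

## What it computes

Per trial, after preprocessing (6 s transient removal, standardisation to
84 s, centring, 10 Hz zero-phase Butterworth low-pass):

* **Coordination stability rho** — instantaneous phases φ₁(t), φ₂(t) from
  the Hilbert analytic signal; relative phase φ = φ₁ − φ₂ wrapped to
  (−180°, 180°]; rho = |⟨e^{iφ(t)}⟩ₜ|, the mean resultant length
  (0 = no synchronisation, 1 = perfect phase locking), plus its Fisher
  transform z = atanh(rho) for modelling.
* **Frequency matching** — Welch-averaged magnitude-squared coherence
  C(f) = |Pxy|²/(Pxx·Pyy), summarised as Σ w(f)·C(f) over 0.2–10 Hz with
  power-proportional weights.
* **Cross-recurrence measures** — both series z-scored and delay-embedded
  (delay from the first AMI minimum, dimension from the first FNN minimum,
  or the conventional (24, 7) at 50 Hz); recurrence matrix
  R[i,j] = 1{‖xᵢ − yⱼ‖ ≤ r} with r tuned by bisection to a 5% recurrence
  rate; **%REC** (percentage of recurrent cells) and **MaxLine** (longest
  diagonal run ≥ 2).
* **Gaze proportion** — share of the trial spent looking at the partner,
  from an avatar/room/missing AOI series.

The inference layer fits linear mixed models with a by-participant random
intercept, Satterthwaite degrees of freedom, simple-slopes decomposition
(moderator at M ± 1 SD, or both levels of a 0/1 code) and Tukey-adjusted
cell contrasts. A stochastic Kuramoto dyad generator —
dθ = (ω + K sin(θₐ − θ)) dt + σ dW with condition- and covariate-dependent
coupling K — produces complete synthetic studies (movement CSVs, gaze
CSVs, covariates, ground-truth coupling) for testing and calibration.

## Worked example

Simulate one spontaneous trial for a participant in the direct-gaze
condition and reduce it to its coordination metrics:

```r
library(dyadsync)
cfg <- sim_config(seed = 7)
row <- data.frame(participant_id = "p001", gaze_condition = "direct",
                  lsas = 48, aq = 12)
sim <- simulate_dyad_trial(row, "spontaneous", cfg, seed = 7)
m <- trial_metrics(sim$pair, crqa = crqa_params(delay = 24, dim = 7))
round(m, 3)
#>     rho rho_z coherence rec_pct maxline radius_used delay dim
#> 1 0.881 1.381     0.859   4.927     218        0.95    24   7
sim$truth$K
#> [1] 0.995
```

A dyad coupled at K ≈ 1 rad/s phase-locks imperfectly: rho 0.88 means the
relative phase stays concentrated but occasionally slips; coherence 0.86
says most movement energy is frequency-matched; the tuned radius (0.95
pooled-SD units) yields the 5% target recurrence rate, and the longest
shared trajectory stretch (MaxLine) spans 218 samples ≈ 4.4 s.

The `analysis/` scripts run the same machinery at study scale:
`01_simulate_study.R` writes a synthetic study under `results/study/`,
`02_compute_metrics.R` reduces it to `results/metrics.csv` (one row per
participant × trial), `03_fit_models.R` fits the full model family and
writes tidy coefficient/slope/contrast CSVs under `results/models/`, and
`04_coupling_monotonicity.R` tabulates how all four metrics grow with the
generative coupling strength.

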