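---
title: "Quantifying dyadic movement coordination: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic movement coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

`dyadsync` turns paired rhythmic movement recordings — a participant and a
virtual partner performing paced arm curls — into coordination indices, and
models how those indices depend on experimental condition, gaze behaviour
and symptom covariates. This vignette explains the models and the choices
behind them; it is the place where every tunable default is justified.

## The measurement problem

Each trial yields two 1-D displacement series sampled at 50 Hz for 90 s,
with movement paced at an 84 bpm metronome (1.4 Hz). Coordination between
the two movers is not one number: the field distinguishes the overall
stability of the phase relation (rho), the degree of frequency matching
(cross-spectral coherence), and the nonlinear structure of shared dynamics
(cross-recurrence measures, here %REC and MaxLine). The package computes
all four per trial, then feeds them to a mixed-effects inference layer.

## Preprocessing

Each trace passes through four steps, in order: the first 6 s are removed
(movement-initiation transient), the remainder is standardised to 84 s,
the series is centred on zero, and a 10 Hz low-pass Butterworth filter is
applied forward-backward (`signal::filtfilt`), so the design order of 2
acts as an effective order 4 with zero phase lag. Choices worth noting:

* **Length standardisation.** With 90 s trials the 6 s trim leaves exactly
  84 s, so standardisation is a no-op; for real files that jitter, longer
  inputs are truncated to the first 84 s and shorter ones linearly
  resampled onto a 4200-sample grid. Truncation preserves the measured
  dynamics wherever possible; resampling is the least-surprise fallback.
* **Step order.** Whether centring precedes filtering is immaterial for a
  linear zero-phase filter up to edge effects; the chain runs
  trim → standardise → centre → filter and both the cutoff and order are
  configurable through `preprocess_config()`.
* **Filter order.** Order 2 (×2) is the common default in movement
  research; with a 1.4 Hz carrier and a 10 Hz cutoff the pass-band loss at
  the movement frequency is below 0.1%.

## Coordination stability (rho)

Instantaneous phases come from the angle of the analytic signal
(frequency-domain Hilbert transform). The relative phase
φ = φ_participant − φ_avatar is wrapped to (−180°, 180°], and

rho = | mean over t of exp(i·φ(t)) |,

the mean resultant length, on a 0–1 scale where 1 is perfect phase
locking and 0 is no synchronisation. Two conventions matter:

* **Signed, not folded phase.** rho is computed on the signed wrapped
  phase. Folding to [0°, 180°] first would score a dyad that spends half
  its time at +90° and half at −90° as perfectly locked; on the signed
  circle it is correctly dispersed. The folded series is kept for
  descriptive distributions only.
* **Edge discard.** The Hilbert transform is unreliable near the series
  ends; 1 s per end (configurable) is flagged and excluded from the
  statistics.
* **Fisher transformation.** For linear modelling rho is mapped through
  atanh after clipping at 1 − 10⁻⁶, keeping perfect synchrony finite.

## Frequency matching (weighted coherence)

Magnitude-squared coherence |Pxy|²/(Pxx·Pyy) is estimated by Welch
averaging: 1024-sample Hann segments with 50% overlap (≈ 20 s windows,
seven segments per 84 s trial — enough cycles of 1.4 Hz per segment for a
stable estimate, enough segments for the cross term to average). Spectra
are averaged across segments before the ratio is formed; a single-segment
"coherence" is identically 1 and meaningless.

The scalar index is a weighted average of coherence over 0.2–10 Hz, the
band in which arm-movement energy can lie after the low-pass. Weights are
proportional to the mean of the two *band-normalised* auto-spectra. The
normalisation (each auto-spectrum scaled to unit mass over the band before
averaging) keeps the power-weighting intent — frequencies where movement
energy actually lies dominate — while making the index invariant to
rescaling either input, which a raw power average is not. Cross-power and
flat weights are available as configuration alternatives.

## Cross-recurrence quantification

Both processed series are z-scored, so the recurrence radius is expressed
in pooled-SD units, and delay-embedded. The embedding parameters follow
the standard protocol:

* **Delay** — first local minimum of the average mutual information,
  estimated from an equal-width joint histogram with ⌈√N⌉ bins capped at
  64 (the usual bias/variance compromise; configurable). A caution from
  the package's own validation: on noise-free periodic signals the
  histogram AMI curve is jagged and its first local minimum can sit well
  below the quarter-period value that idealised treatments quote; the
  selection rule is therefore defined relative to this estimator, and the
  brute-force reference in the test suite agrees with it exactly.
* **Dimension** — first local minimum of the Kennel false-nearest-
  neighbour fraction (Rtol = 15, Atol = 2 × series SD; the fraction at
  dimension d is computed with the (d+1)-th delay coordinate), with
  threshold-crossing (< 1%) and global-minimum fallbacks.
* **Shared setting.** A study is analysed with one (delay, dimension)
  pair: per-trial estimates are reduced by the across-trial median, or the
  conventional 50 Hz arm-movement setting (delay 24 samples, dimension 7)
  can be fixed by configuration.

The cross-recurrence matrix marks pairs of embedded points within the
radius; %REC is the percentage of recurrent cells and MaxLine the longest
diagonal run of at least 2 consecutive recurrent points. All diagonals are
counted — a cross-recurrence plot between distinct signals has no identity
line to exclude — and the Theiler window is 0. Because published radii are
unit-ambiguous, the primary mechanism is automatic: bisection on the
radius to a 5% target recurrence rate (±0.5 percentage points, ≤ 60
iterations), which is well-defined because the recurrence rate is exactly
monotone in the radius. Long series never materialise the matrix; the
compiled core streams over diagonals.

## Gaze

Area-of-interest series (avatar vs room, with a missing code for blinks
and tracking loss) reduce to the proportion of the trial spent looking at
the avatar. Missing samples are excluded from the denominator by default —
standard eye-tracking practice — with `as_room` available where total
trial time is the intended base. Gaze series are windowed to the same
6–90 s span as the movement data.

## Inference

Outcomes (Fisher-z rho, coherence, %REC, MaxLine) are modelled with linear
mixed models: fixed effects for the 0/1-coded factors (coordination:
0 = spontaneous, 1 = intentional; avatar gaze: 0 = direct, 1 = averted),
at most one questionnaire score per model (LSAS or AQ, mirroring the
separate-model convention), optional participant-gaze terms, and their
interactions; the random structure is a by-participant intercept. All
predictors are centred (constants recorded for back-transformation);
centring relocates the intercept and lower-order terms but leaves the
highest-order interaction untouched, which the tests verify numerically.

Degrees of freedom are Satterthwaite via `lmerTest`; if the machinery is
unavailable for a fit the result records a residual-df fallback, and a
fully degenerate fit (e.g. a zero-variance outcome) is flagged singular
with missing uncertainty rather than fabricated SEs. Interactions are
decomposed two ways: simple slopes of a focal predictor at moderator
levels — mean ± 1 SD for continuous moderators ("low / medium / high",
the conventional reading), both observed values for 0/1 codes — and
Tukey-adjusted pairwise contrasts of estimated marginal means over factor
cells, with non-focal covariates held at their means and a recorded
Bonferroni fallback if the multivariate-t machinery were missing.

Missing questionnaire items are imputed with the respondent's mean over
the observed items of the same subscale before totals are formed, the
standard questionnaire convention; a respondent missing an entire subscale
is reported as an error rather than imputed.

## The synthetic-study generator

The generator exists so every stage is testable without any download, and
doubles as the ground-truth source for parameter-recovery checks. It is a
stochastic Kuramoto pair, not a full HKB model: the simplest generative
form with a tunable, monotone coupling → synchrony relationship. HKB
bistability (anti-phase regimes, phase transitions) is deliberately out of
scope.

* **Avatar**: a 1.4 Hz sinusoid whose instantaneous frequency carries ≤ 1%
  smooth drift (two slow random-phase components), emulating a pre-recorded
  human mover keeping metronome time.
* **Participant**: Euler–Maruyama integration at 50 Hz of
  dθ = (ω + K·sin(θ_avatar − θ)) dt + σ_η dW, with natural frequency
  1.4 Hz plus a per-participant detuning (SD 0.05 Hz), phase-diffusion
  σ_η = 0.7 rad/√s, and additive measurement noise (SD 0.05 of unit
  amplitude). These values put an uncoupled dyad near rho ≈ 0.2 and a
  strongly coupled one (K ≥ 4 rad/s) above 0.95, spanning the observable
  range.
* **Coupling**: K = K₀ + ΔK_int·[intentional] + ΔK_dir·[direct]
  + β_LSAS,averted·LSAS_c·[averted] + β_LSAS,direct·LSAS_c·[direct]
  + β_AQ·AQ_c, floored at zero (the floor is recorded in the truth table).
  Defaults (K₀ = 0.6, ΔK_int = 3, ΔK_dir = 0.4, β_LSAS,averted = +0.008,
  β_LSAS,direct = −0.002, β_AQ = −0.01 rad/s per centred point) were fixed
  once to reproduce the qualitative pattern of the target design — a
  gaze benefit in spontaneous trials that washes out under intentional
  coordination (near-ceiling coupling), and a positive LSAS relation only
  under averted gaze. No published effect sizes exist in these units, so
  the magnitudes are the package's own calibration and are not revisited.
* **Covariates**: LSAS and AQ are truncated normals on the published
  ranges (9–119, 1–25) whose parent parameters are solved numerically so
  the *truncated* mean and SD equal the published sample moments
  (M = 55.43, SD = 23.52; M = 9.99, SD = 4.83); scores are rounded to
  whole points. Gaze condition is balanced ⌈n/2⌉/⌊n/2⌋.
* **Gaze behaviour**: a two-state Markov chain whose stationary
  avatar-probability is logistic in condition shifts and centred AQ, with
  geometric dwells (switch intensity 0.04 per sample ≈ 1–2 s dwells).
  Movement coupling and gaze are linked only through shared covariates,
  mirroring the separate analyses they feed.

What the generator does *not* emulate: amplitude dynamics and movement
harmonics, non-stationary strategies (drifting attention, fatigue),
anti-phase coordination, eye-movement kinematics, or item-level
questionnaire responses. Tests passing on synthetic data therefore
demonstrate that the measurement chain recovers known coupling structure
under the stated noise model — not that any particular empirical effect in
real data is true.

## Numerical and scale choices in the validation suite

Property checks that average over many simulated dyads use shortened
trials (30–40 s instead of 90 s) and fixed embedding settings so the full
suite stays fast; the coupling-monotonicity check runs the K grid
{0, 0.5, 1, 2, 4} rad/s at 50 seeds per level, parameter-recovery runs 100
replicates at the 134-participant design, and the null-calibration runs
500 scaled-down replicates at 40 participants. Exact-agreement oracle
checks (AMI, FNN, recurrence rate, MaxLine against naive brute-force
implementations) use 50 random series of length ≤ 200, where exhaustive
computation is cheap.

## Known limitations

* The coherence weighting resolves a genuine ambiguity ("weighted
  average" is underdetermined); alternative weightings are exposed but
  change the index's absolute level.
* Histogram AMI on strongly periodic, low-noise signals has unstable
  first minima (see above); when analysing clean periodic data, fixing the
  embedding to the conventional (24, 7) is the safer route, and the
  pipeline makes that a one-line override.
* The radius-in-published-units question is sidestepped, not answered:
  the tuner reproduces the target recurrence rate, so any fixed radius in
  unknown units is only honoured if supplied explicitly.
* Satterthwaite p-values on 40-participant null simulations run very
  slightly conservative-to-nominal; the suite checks the 3–7% band around
  the nominal 5%.
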