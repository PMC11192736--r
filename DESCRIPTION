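Package: dyadsync
Title: Coordination Dynamics of Dyadic Rhythmic Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies interpersonal movement coordination from paired
    rhythmic displacement time series and models condition and symptom
    effects on the resulting indices. Implements the full reduction chain
    (transient trimming, length standardisation, centring, zero-phase
    Butterworth low-pass), Hilbert-transform relative phase and its
    circular stability index rho, weighted cross-spectral coherence,
    and cross-recurrence quantification (delay embedding via average
    mutual information and false nearest neighbours, recurrence rate,
    MaxLine, automatic radius selection to a target recurrence rate),
    plus gaze area-of-interest dwell proportions. An inference layer fits
    by-participant random-intercept mixed models with Satterthwaite
    degrees of freedom, simple-slopes decomposition and Tukey-adjusted
    contrasts. A stochastic coupled phase-oscillator generator produces
    complete synthetic studies for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    lme4,
    lmerTest,
    emmeans,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
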