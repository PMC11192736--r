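#!/usr/bin/env Rscript
# Mixed-effects inference over the study table.
#
# For each coordination outcome (Fisher-z rho, coherence, %REC, MaxLine):
# a condition model (coordination x avatar gaze), one model per
# questionnaire (adding its centred score and all interactions), a
# participant-gaze model, and participant-gaze x questionnaire models.
# Every model carries a by-participant random intercept; df are
# Satterthwaite; interactions are decomposed with simple slopes and
# Tukey-adjusted cell contrasts. Tidy CSVs land under results/models/.

library(dyadsync)

tab <- read.csv("results/metrics.csv")
cfg <- run_config("results/study", "results",
                  outcomes = c("rho_z", "coherence", "rec_pct", "maxline"))

res <- run_analysis(tab, cfg)

ok <- vapply(res, function(r) !is.null(r) && r$converged, logical(1))
message(sprintf("fitted %d models (%d converged)", length(res), sum(ok)))

cond <- res$rho_z_condition
if (!is.null(cond)) {
  message("rho_z ~ coordination x gaze:")
  print(cond$coefficients, digits = 3)
}
sl <- file.path("results/models", "rho_z_lsas_slopes.csv")
if (file.exists(sl)) {
  message("LSAS simple slopes on rho_z by gaze condition:")
  print(read.csv(sl), digits = 3)
}
message("full tables in results/models/; settings in results/run.log")
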