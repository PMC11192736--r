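#' Run configuration for an end-to-end study analysis
#'
#' @param input_dir Study directory ([generate_study] layout: per-trial
#'   `<id>_<trial>_movement.csv` / `<id>_<trial>_gaze.csv` plus
#'   `covariates.csv`).
#' @param output_dir Where `metrics.csv`, `models/` and `run.log` go.
#' @param preprocess A [preprocess_config].
#' @param spectral A [spectral_config].
#' @param crqa A [crqa_params]; leave `delay`/`dim` `NULL` to estimate them
#'   per trial and share the across-trial median, or set them (e.g. the
#'   conventional 7 and 24 at 50 Hz) to skip estimation.
#' @param outcomes Outcome columns to model.
#' @param seed Seed recorded for the run.
#' @param verbose Emit progress messages.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, output_dir,
                       preprocess = preprocess_config(),
                       spectral = spectral_config(),
                       crqa = crqa_params(),
                       outcomes = c("rho_z", "coherence", "rec_pct", "maxline"),
                       seed = 1L, verbose = FALSE) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 preprocess = preprocess, spectral = spectral, crqa = crqa,
                 outcomes = outcomes, seed = seed, verbose = verbose),
            class = "run_config")
}

#' Compute all per-trial coordination metrics for one trial pair
#'
#' @param pair A raw [trial_pair].
#' @param preprocess,spectral,crqa Stage configurations.
#' @return One-row data.frame: rho, rho_z, coherence, rec_pct, maxline,
#'   radius_used, delay, dim.
#' @export
trial_metrics <- function(pair, preprocess = preprocess_config(),
                          spectral = spectral_config(),
                          crqa = crqa_params()) {
  proc <- preprocess_trial(pair, preprocess)
  ph <- dyad_phase_metrics(proc)
  coh <- weighted_coherence(
    cross_spectra(proc$participant, proc$avatar, config = spectral))
  cr <- dyad_crqa_metrics(proc, crqa)
  data.frame(rho = ph$rho, rho_z = ph$rho_z, coherence = coh,
             rec_pct = cr$rec_pct, maxline = cr$maxline,
             radius_used = cr$radius_used, delay = cr$delay, dim = cr$dim)
}

#' Compute the study table of coordination metrics
#'
#' One row per participant x trial: rho, Fisher-z rho, weighted coherence,
#' %REC, MaxLine, gaze proportion, plus the 0/1 condition codes
#' (coordination: 0 = spontaneous, 1 = intentional; gaze: 0 = direct,
#' 1 = averted) and centred predictors. Per-trial failures are logged and
#' left as missing rows; they never abort the batch.
#'
#' When the CRQA `delay`/`dim` are unset, they are first estimated per
#' trial and the across-trial medians are applied to every trial, mirroring
#' the single shared embedding setting of the movement-coordination
#' literature.
#'
#' @param config A [run_config].
#' @return The study table (data.frame) with attribute `log` (character).
#' @export
compute_metrics <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cov_path <- file.path(config$input_dir, "covariates.csv")
  if (!file.exists(cov_path)) {
    stop("input error: no covariates.csv in ", config$input_dir,
         call. = FALSE)
  }
  cov <- read_covariates_csv(cov_path)
  trials <- expand.grid(participant_id = cov$participant_id,
                        coordination = c("spontaneous", "intentional"),
                        stringsAsFactors = FALSE)
  trials <- trials[order(trials$participant_id), ]
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (config$verbose) message(msg)
  }

  load_pair <- function(pid, trial_type) {
    stem <- file.path(config$input_dir, sprintf("%s_%s", pid, trial_type))
    gc <- cov$gaze_condition[cov$participant_id == pid]
    pair <- read_pair_csv(paste0(stem, "_movement.csv"),
                          gaze_condition = gc, coordination = trial_type,
                          trial_id = sprintf("%s_%s", pid, trial_type))
    preprocess_trial(pair, config$preprocess)
  }

  crqa <- config$crqa
  if (is.null(crqa$delay) || is.null(crqa$dim)) {
    est <- lapply(seq_len(nrow(trials)), function(k) {
      tryCatch({
        proc <- load_pair(trials$participant_id[k], trials$coordination[k])
        ex <- estimate_embedding(as.numeric(scale(proc$participant$x)))
        ey <- estimate_embedding(as.numeric(scale(proc$avatar$x)))
        c(delay = stats::median(c(ex$delay, ey$delay)),
          dim = max(ex$dim, ey$dim))
      }, error = function(e) c(delay = NA_real_, dim = NA_real_))
    })
    est <- do.call(rbind, est)
    if (all(is.na(est[, "delay"]))) {
      stop("input error: embedding estimation failed on every trial",
           call. = FALSE)
    }
    if (is.null(crqa$delay)) {
      crqa$delay <- round(stats::median(est[, "delay"], na.rm = TRUE))
    }
    if (is.null(crqa$dim)) {
      crqa$dim <- round(stats::median(est[, "dim"], na.rm = TRUE))
    }
    say("shared embedding estimated: delay=%d samples, dim=%d",
        crqa$delay, crqa$dim)
  } else {
    say("shared embedding fixed by config: delay=%d, dim=%d",
        crqa$delay, crqa$dim)
  }

  rows <- lapply(seq_len(nrow(trials)), function(k) {
    pid <- trials$participant_id[k]
    trial_type <- trials$coordination[k]
    base <- data.frame(participant_id = pid, trial = trial_type,
                       rho = NA_real_, rho_z = NA_real_,
                       coherence = NA_real_, rec_pct = NA_real_,
                       maxline = NA_real_, gaze_prop = NA_real_,
                       radius_used = NA_real_)
    m <- tryCatch({
      proc <- load_pair(pid, trial_type)
      ph <- dyad_phase_metrics(proc)
      coh <- weighted_coherence(
        cross_spectra(proc$participant, proc$avatar,
                      config = config$spectral))
      cr <- dyad_crqa_metrics(proc, crqa)
      base$rho <- ph$rho; base$rho_z <- ph$rho_z; base$coherence <- coh
      base$rec_pct <- cr$rec_pct; base$maxline <- cr$maxline
      base$radius_used <- cr$radius_used
      base
    }, error = function(e) {
      say("trial %s_%s failed: %s", pid, trial_type, conditionMessage(e))
      base
    })
    gz_path <- file.path(config$input_dir,
                         sprintf("%s_%s_gaze.csv", pid, trial_type))
    if (file.exists(gz_path)) {
      m$gaze_prop <- tryCatch(
        gaze_proportion(read_aoi_csv(gz_path),
                        window = c(config$preprocess$trim_s, Inf)),
        error = function(e) {
          say("gaze %s_%s failed: %s", pid, trial_type, conditionMessage(e))
          NA_real_
        })
    }
    m
  })
  tab <- do.call(rbind, rows)
  tab <- merge(tab, cov, by = "participant_id", sort = TRUE)
  tab <- build_codes(tab)
  say("metrics computed for %d trials (%d with missing cells)",
      nrow(tab), sum(!stats::complete.cases(tab)))
  attr(tab, "log") <- log
  attr(tab, "crqa") <- crqa
  tab
}

#' Add 0/1 factor codes and centred predictors to a study table
#'
#' Coordination: 0 = spontaneous, 1 = intentional; gaze: 0 = direct,
#' 1 = averted. Each numeric predictor gains a centred `_c` twin; centring
#' constants are stored in attribute `centers`.
#'
#' @param tab Data.frame with columns `trial` (or `coordination` already
#'   coded) and `gaze_condition`, plus `lsas`, `aq`, optionally `gaze_prop`.
#' @return The augmented table.
#' @export
build_codes <- function(tab) {
  tab$coordination <- as.integer(tab$trial == "intentional")
  tab$gaze <- as.integer(tab$gaze_condition == "averted")
  num <- intersect(c("coordination", "gaze", "lsas", "aq", "gaze_prop"),
                   names(tab))
  cent <- center_predictors(tab[, num, drop = FALSE], num)
  for (cl in num) tab[[paste0(cl, "_c")]] <- cent[[cl]]
  attr(tab, "centers") <- attr(cent, "centers")
  tab
}

#' Fit the full model family to a study table
#'
#' Mirrors the inference battery of the design: for each outcome, (1) a
#' condition-only model `outcome ~ coordination x gaze`; (2) one model per
#' questionnaire adding its centred score and all interactions; (3) a
#' participant-gaze model; and (4) one gaze x questionnaire model per
#' questionnaire. All models carry a by-participant random intercept.
#' Coefficient tables, simple-slope tables for the questionnaire models and
#' Tukey-adjusted cell contrasts for the condition models are written as
#' tidy CSVs under `output_dir/models/`, with a run log of the settings in
#' effect.
#'
#' @param table A study table from [compute_metrics] (or
#'   [simulate_study_table] plus [build_codes]).
#' @param config A [run_config] (only `output_dir`, `outcomes`, `verbose`
#'   used), or `NULL` to skip writing.
#' @return Named list of `model_result` objects, invisibly; failures are
#'   reported per model and do not abort the set.
#' @export
run_analysis <- function(table, config = NULL) {
  outcomes <- if (is.null(config)) {
    intersect(c("rho_z", "coherence", "rec_pct", "maxline"), names(table))
  } else config$outcomes
  missing_out <- setdiff(outcomes, names(table))
  if (length(missing_out)) {
    stop("spec error: outcome(s) not in table: ",
         paste(missing_out, collapse = ", "), call. = FALSE)
  }
  out_dir <- if (!is.null(config)) file.path(config$output_dir, "models")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  log <- character(0)
  results <- list()
  has_gaze <- "gaze_prop_c" %in% names(table) &&
    any(is.finite(table$gaze_prop_c))

  specs <- list()
  for (y in outcomes) {
    specs[[paste0(y, "_condition")]] <-
      stats::as.formula(paste(y, "~ coordination_c * gaze_c"))
    for (q in c("lsas_c", "aq_c")) {
      specs[[paste0(y, "_", sub("_c$", "", q))]] <-
        stats::as.formula(paste(y, "~ coordination_c * gaze_c *", q))
    }
    if (has_gaze) {
      specs[[paste0(y, "_participant_gaze")]] <-
        stats::as.formula(paste(y, "~ gaze_prop_c + coordination_c + gaze_c"))
      for (q in c("lsas_c", "aq_c")) {
        specs[[paste0(y, "_gaze_x_", sub("_c$", "", q))]] <-
          stats::as.formula(
            paste(y, "~ gaze_prop_c *", q, "+ coordination_c + gaze_c"))
      }
    }
  }

  for (nm in names(specs)) {
    res <- tryCatch(
      suppressWarnings(fit_lmm(stats::na.omit(
        table[, c("participant_id", all.vars(specs[[nm]]))]),
        specs[[nm]])),
      error = function(e) {
        log <<- c(log, sprintf("model %s failed: %s", nm,
                               conditionMessage(e)))
        NULL
      })
    results[[nm]] <- res
    if (is.null(res)) next
    log <- c(log, sprintf("model %s: df=%s%s", nm, res$df_method,
                          if (res$singular) " (singular)" else ""))
    if (!is.null(out_dir)) {
      utils::write.csv(res$coefficients,
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
      if (grepl("_condition$", nm)) {
        ct <- pairwise_contrasts(res, c("coordination_c", "gaze_c"))
        utils::write.csv(ct, file.path(out_dir, paste0(nm, "_contrasts.csv")),
                         row.names = FALSE)
      }
      if (grepl("_(lsas|aq)$", nm)) {
        q <- paste0(sub(".*_", "", nm), "_c")
        ss <- simple_slopes(res, focal = q, moderator = "gaze_c")
        utils::write.csv(ss, file.path(out_dir, paste0(nm, "_slopes.csv")),
                         row.names = FALSE)
      }
    }
  }
  if (!is.null(config)) {
    log <- c(sprintf("run seed=%s; outcomes=%s", config$seed,
                     paste(outcomes, collapse = ",")),
             sprintf("preprocess: trim=%gs target=%gs butterworth order %d (x2 zero-phase) cutoff %g Hz",
                     config$preprocess$trim_s, config$preprocess$target_s,
                     config$preprocess$filter_order,
                     config$preprocess$cutoff_hz),
             sprintf("coherence weights=%s band=%g-%g Hz",
                     config$spectral$weights, config$spectral$band[1],
                     config$spectral$band[2]),
             sprintf("crqa: min_line=%d target_rr=%g%% radius=%s",
                     config$crqa$min_line, config$crqa$target_rr,
                     if (is.null(config$crqa$radius)) "tuned" else
                       config$crqa$radius),
             log)
    writeLines(log, file.path(config$output_dir, "run.log"))
  }
  attr(results, "log") <- log
  invisible(results)
}
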