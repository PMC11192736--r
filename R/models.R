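#' Impute missing questionnaire items with the respondent's subscale mean
#'
#' Each missing item is replaced by that respondent's mean over the observed
#' items of the same subscale; a respondent missing an entire subscale
#' cannot be imputed and raises an error.
#'
#' @param item_table Data.frame, one row per respondent, item columns
#'   numeric; non-item columns are preserved.
#' @param subscales Named list mapping subscale name to its item column
#'   names.
#' @return The completed item table, with a numeric attribute `total`
#'   (row sums over all items, recomputed after imputation).
#' @export
impute_subscale_mean <- function(item_table, subscales) {
  items <- unlist(subscales, use.names = FALSE)
  missing_cols <- setdiff(items, names(item_table))
  if (length(missing_cols)) {
    stop("spec error: unknown item column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- item_table
  for (r in seq_len(nrow(out))) {
    for (sc in names(subscales)) {
      cols <- subscales[[sc]]
      vals <- as.numeric(out[r, cols])
      miss <- is.na(vals)
      if (all(miss)) {
        stop(sprintf("imputation error: respondent %d is missing all of subscale '%s'",
                     r, sc), call. = FALSE)
      }
      if (any(miss)) {
        out[r, cols[miss]] <- mean(vals[!miss])
      }
    }
  }
  attr(out, "total") <- rowSums(out[, items, drop = FALSE])
  out
}

#' Centre predictor columns
#'
#' Subtracts the sample mean from each listed column; the centring constants
#' are recorded in attribute `centers` for back-transformation.
#'
#' @param table Data.frame.
#' @param columns Character vector of numeric columns to centre.
#' @return The table with centred columns and attribute `centers`.
#' @export
center_predictors <- function(table, columns) {
  centers <- numeric(0)
  for (cl in columns) {
    if (!is.numeric(table[[cl]])) {
      stop("type error: column '", cl, "' is not numeric", call. = FALSE)
    }
    centers[cl] <- mean(table[[cl]], na.rm = TRUE)
    table[[cl]] <- table[[cl]] - centers[cl]
  }
  attr(table, "centers") <- centers
  table
}

#' Fit a by-participant random-intercept mixed model
#'
#' REML fit of `outcome ~ fixed terms + (1 | participant_id)` with
#' Satterthwaite degrees of freedom where the backend provides them
#' (residual df otherwise, recorded in the result).
#'
#' @param table A study table (one row per participant x trial).
#' @param fixed One-sided or two-sided formula giving the fixed effects,
#'   e.g. `rho_z ~ coordination * gaze`.
#' @param group Grouping column for the random intercept
#'   (default `"participant_id"`).
#' @return A `model_result`: list with `model`, `coefficients` (term,
#'   estimate, se, df, t, p), `varcor`, `logLik`, `converged`, `singular`,
#'   `df_method`.
#' @export
fit_lmm <- function(table, fixed, group = "participant_id") {
  stopifnot(inherits(fixed, "formula"), nrow(table) >= 2)
  if (!group %in% names(table)) {
    stop("spec error: grouping column '", group, "' absent", call. = FALSE)
  }
  full <- stats::as.formula(
    paste(deparse(fixed[[2]]), "~", deparse(fixed[[3]]),
          sprintf("+ (1 | %s)", group)))
  quiet_fit <- function(expr) {
    withCallingHandlers(
      expr,
      warning = function(w) {
        if (grepl("singular", conditionMessage(w), ignore.case = TRUE)) {
          invokeRestart("muffleWarning")
        }
      },
      message = function(m) {
        if (grepl("singular", conditionMessage(m), ignore.case = TRUE)) {
          invokeRestart("muffleMessage")
        }
      })
  }
  # lmerTest's Satterthwaite machinery can fail on degenerate fits
  # (e.g. zero-variance outcomes); fall back to the plain lme4 fit then.
  fit <- tryCatch(
    quiet_fit(lmerTest::lmer(full, data = table, REML = TRUE)),
    error = function(e) quiet_fit(lme4::lmer(full, data = table, REML = TRUE)))
  opt_ok <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  if (!opt_ok) {
    stop("non-convergence: optimizer reported code ",
         fit@optinfo$conv$opt, "; messages: ",
         paste(unlist(fit@optinfo$conv$lme4), collapse = "; "),
         call. = FALSE)
  }
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("singular fit: random-intercept variance is (near) zero",
            call. = FALSE)
  }
  ct <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(ct)) {
    # fully degenerate fit: even the covariance of the fixed effects is
    # unavailable; report the estimates with the uncertainty marked missing
    est <- lme4::fixef(fit)
    coefs <- data.frame(term = names(est), estimate = unname(est),
                        se = NA_real_, df = NA_real_, t = NA_real_,
                        p = NA_real_, row.names = NULL)
    df_method <- "unavailable"
    if (!singular) {
      singular <- TRUE
      warning("singular/degenerate fit: coefficient covariance unavailable",
              call. = FALSE)
    }
  } else {
    if ("df" %in% colnames(ct)) {
      df_method <- "satterthwaite"
    } else {
      # residual-df fallback when Satterthwaite machinery is unavailable
      rdf <- nrow(table) - nrow(ct)
      ct <- cbind(ct[, 1:2, drop = FALSE], df = rdf,
                  `t value` = ct[, "t value"],
                  `Pr(>|t|)` = 2 * stats::pt(-abs(ct[, "t value"]), rdf))
      df_method <- "residual"
      message("Satterthwaite df unavailable; residual df used")
    }
    coefs <- data.frame(term = rownames(ct),
                        estimate = ct[, "Estimate"],
                        se = ct[, "Std. Error"],
                        df = ct[, "df"],
                        t = ct[, "t value"],
                        p = ct[, "Pr(>|t|)"],
                        row.names = NULL)
  }
  structure(list(model = fit, coefficients = coefs,
                 varcor = lme4::VarCorr(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 converged = opt_ok, singular = singular,
                 df_method = df_method),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> df=%s%s%s\n", x$df_method,
              if (x$singular) ", singular" else "",
              if (!x$converged) ", NOT CONVERGED" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Simple slopes of a focal predictor at moderator levels
#'
#' Conditional slope of `focal` at chosen values of `moderator`. For a
#' continuous moderator the default levels are mean - SD, mean, mean + SD
#' ("low / medium / high"); for a 0/1 factor code, its two observed values.
#' Degrees of freedom follow the fitted model's method.
#'
#' @param result A `model_result` whose model contains the
#'   `focal:moderator` interaction.
#' @param focal Name of the focal predictor column.
#' @param moderator Name of the moderator column.
#' @param levels Moderator values at which to evaluate; `NULL` for the
#'   defaults above.
#' @return Data.frame with moderator level, slope, SE, df, t, p.
#' @export
simple_slopes <- function(result, focal, moderator, levels = NULL) {
  stopifnot(inherits(result, "model_result"))
  mf <- stats::model.frame(result$model)
  for (v in c(focal, moderator)) {
    if (!v %in% names(mf)) {
      stop("spec error: '", v, "' is not in the fitted model", call. = FALSE)
    }
  }
  if (is.null(levels)) {
    vals <- mf[[moderator]]
    uni <- sort(unique(vals))
    if (length(uni) == 2) {
      levels <- uni
    } else {
      levels <- mean(vals) + c(-1, 0, 1) * stats::sd(vals)
    }
  }
  at <- stats::setNames(list(levels), moderator)
  tr <- emmeans::emtrends(result$model, specs = moderator, var = focal,
                          at = at, lmer.df = "satterthwaite")
  s <- summary(tr, infer = c(FALSE, TRUE))
  data.frame(moderator = moderator, level = s[[1]],
             slope = s[[paste0(focal, ".trend")]],
             se = s$SE, df = s$df, t = s$t.ratio, p = s$p.value,
             row.names = NULL)
}

#' Multiplicity-adjusted pairwise contrasts across factor cells
#'
#' Estimated marginal means over the crossed levels of the listed 0/1
#' factor codes (non-focal covariates held at their means), compared
#' pairwise with Tukey adjustment where the multivariate-t machinery is
#' available, Bonferroni otherwise.
#'
#' @param result A `model_result`.
#' @param factors Character vector of factor-code columns in the model.
#' @param adjust Adjustment method (default `"tukey"`).
#' @return Data.frame of contrasts (contrast, estimate, SE, df, t, p) with
#'   attribute `adjust_used`.
#' @export
pairwise_contrasts <- function(result, factors, adjust = "tukey") {
  stopifnot(inherits(result, "model_result"))
  mf <- stats::model.frame(result$model)
  missing_f <- setdiff(factors, names(mf))
  if (length(missing_f)) {
    stop("spec error: factor(s) not in model: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  at <- lapply(factors, function(f) sort(unique(mf[[f]])))
  names(at) <- factors
  spec <- stats::as.formula(paste("~", paste(factors, collapse = " * ")))
  em <- emmeans::emmeans(result$model, spec, at = at, cov.reduce = mean,
                         lmer.df = "satterthwaite")
  pr <- tryCatch(
    summary(emmeans::contrast(em, method = "pairwise", adjust = adjust)),
    error = function(e) {
      message("Tukey adjustment unavailable (", conditionMessage(e),
              "); falling back to Bonferroni")
      summary(emmeans::contrast(em, method = "pairwise",
                                adjust = "bonferroni"))
    })
  adjust_used <- attr(pr, "adjust") %||%
    (if (!is.null(pr$p.value)) adjust else "none")
  out <- data.frame(contrast = as.character(pr$contrast),
                    estimate = pr$estimate, se = pr$SE, df = pr$df,
                    t = pr$t.ratio, p = pr$p.value, row.names = NULL)
  attr(out, "adjust_used") <- adjust_used
  out
}
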