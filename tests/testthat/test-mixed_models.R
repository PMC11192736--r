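test_that("subscale-mean imputation fills gaps and recomputes totals", {
  it <- data.frame(a1 = c(2, 1, 5), a2 = c(4, NA, 5), a3 = c(NA, 2, 5),
                   b1 = c(1, 1, NA), b2 = c(3, 3, NA))
  subs <- list(A = c("a1", "a2", "a3"), B = c("b1", "b2"))
  full <- it[1:2, ]
  full[1, "a3"] <- 3; full[2, "a2"] <- 1.5
  out <- impute_subscale_mean(it[1:2, ], subs)
  expect_equal(out, full, ignore_attr = TRUE)
  expect_equal(unname(attr(out, "total")), c(13, 8.5))
  no_miss <- impute_subscale_mean(full, subs)
  expect_equal(no_miss, full, ignore_attr = TRUE)
  expect_error(impute_subscale_mean(it, subs), "imputation error")
})

test_that("centring zeroes means, records constants and is idempotent", {
  tab <- data.frame(lsas = c(30, 60, 90), code = c(0, 0, 1),
                    lab = c("a", "b", "c"))
  out <- center_predictors(tab, c("lsas", "code"))
  expect_equal(mean(out$lsas), 0, tolerance = 1e-9)
  expect_equal(attr(out, "centers"), c(lsas = 60, code = 1 / 3))
  expect_equal(out$code, c(-1, -1, 2) / 3)
  again <- center_predictors(out, "lsas")
  expect_equal(again$lsas, out$lsas)
  expect_error(center_predictors(tab, "lab"), "type error")
})

test_that("the intercept-only mixed model recovers the grand mean", {
  tab <- simulate_study_table(40, seed = 30)
  fit <- fit_lmm(tab, y ~ 1)
  expect_equal(fit$coefficients$estimate[1], mean(tab$y), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$df_method, "satterthwaite")
})

test_that("fixed effects match OLS when the random intercept is null", {
  tab <- simulate_study_table(60, coefs = list(sd_u = 0), seed = 31)
  fit <- suppressWarnings(fit_lmm(tab, y ~ coordination * gaze))
  ols <- stats::lm(y ~ coordination * gaze, data = tab)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 0.02)
  expect_lt(as.numeric(lme4::VarCorr(fit$model)$participant_id[1]), 0.01)
})

test_that("a zero-variance outcome is flagged as singular", {
  tab <- simulate_study_table(20, seed = 32)
  tab$y <- 1
  expect_warning(fit <- fit_lmm(tab, y ~ coordination), "singular")
  expect_true(fit$singular)
})

test_that("known coefficients are recovered within 2 SE in most replicates", {
  hits <- vapply(1:25, function(s) {
    tab <- simulate_study_table(60, coefs = list(b_gaze = -0.2), seed = 400 + s)
    fit <- suppressWarnings(fit_lmm(tab, y ~ coordination + gaze))
    co <- fit$coefficients
    abs(co$estimate[co$term == "gaze"] - (-0.2)) <=
      2 * co$se[co$term == "gaze"]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("centring predictors moves the intercept, not the top interaction", {
  tab <- simulate_study_table(50, seed = 33)
  raw <- suppressWarnings(fit_lmm(tab, y ~ coordination * gaze))
  cent <- suppressWarnings(
    fit_lmm(build_codes_table_for_test(tab), y ~ coordination_c * gaze_c))
  term_raw <- raw$coefficients[raw$coefficients$term == "coordination:gaze", ]
  term_c <- cent$coefficients[
    cent$coefficients$term == "coordination_c:gaze_c", ]
  expect_equal(term_raw$estimate, term_c$estimate, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(
    raw$coefficients$estimate[1], cent$coefficients$estimate[1])))
})

test_that("no-moderation models give identical simple slopes at all levels", {
  tab <- simulate_study_table(50, coefs = list(b_cg = 0), seed = 34)
  # deterministic outcome with no interaction term at all
  tab$y <- 1 + 0.5 * tab$coordination - 0.2 * tab$gaze
  fit0 <- suppressWarnings(fit_lmm(tab, y ~ coordination * gaze))
  ss <- simple_slopes(fit0, focal = "gaze", moderator = "coordination")
  expect_equal(ss$slope[1], ss$slope[2], tolerance = 1e-6)
  expect_error(simple_slopes(fit0, "gaze", "lsas_c"), "not in the fitted")
})

test_that("factor-moderator simple slopes match subset refits", {
  tab <- simulate_study_table(80, coefs = list(b_lsas = 0.004,
                                               b_lsas_gaze = 0.006),
                              seed = 35)
  fit <- suppressWarnings(fit_lmm(tab, y ~ gaze * lsas_c))
  ss <- simple_slopes(fit, focal = "lsas_c", moderator = "gaze")
  for (g in c(0, 1)) {
    sub <- tab[tab$gaze == g, ]
    ref <- suppressWarnings(fit_lmm(sub, y ~ lsas_c))
    expect_equal(ss$slope[ss$level == g],
                 ref$coefficients$estimate[ref$coefficients$term == "lsas_c"],
                 tolerance = 1e-3)
  }
})

test_that("built-in moderated slopes are detected where the generator puts them", {
  detect <- vapply(1:20, function(s) {
    tab <- simulate_study_table(
      120, coefs = list(b_lsas = 0, b_lsas_gaze = 0.008), seed = 600 + s)
    fit <- suppressWarnings(fit_lmm(tab, y ~ gaze * lsas_c))
    ss <- simple_slopes(fit, "lsas_c", "gaze")
    c(averted_pos = ss$p[ss$level == 1] < 0.05 && ss$slope[ss$level == 1] > 0,
      direct_null = abs(ss$slope[ss$level == 0]) <= 2 * ss$se[ss$level == 0])
  }, logical(2))
  expect_gte(mean(detect["averted_pos", ]), 0.8)
  expect_gte(mean(detect["direct_null", ]), 0.8)
})

test_that("two-level contrasts equal the coefficient with no adjustment cost", {
  tab <- simulate_study_table(40, seed = 36)
  fit <- suppressWarnings(fit_lmm(tab, y ~ coordination))
  ct <- pairwise_contrasts(fit, "coordination")
  co <- fit$coefficients
  expect_equal(abs(ct$estimate),
               abs(co$estimate[co$term == "coordination"]),
               tolerance = 1e-8)
  expect_equal(ct$p, co$p[co$term == "coordination"], tolerance = 1e-6)
  expect_error(pairwise_contrasts(fit, "nonexistent"), "spec error")
})

test_that("identical cell means give near-zero contrasts", {
  tab <- simulate_study_table(40, coefs = list(b_coord = 0, b_gaze = 0,
                                               b_cg = 0, sd_u = 0.01,
                                               sd_e = 0.01),
                              seed = 37)
  fit <- suppressWarnings(fit_lmm(tab, y ~ coordination * gaze))
  ct <- pairwise_contrasts(fit, c("coordination", "gaze"))
  expect_true(all(abs(ct$estimate) < 0.02))
})

test_that("Tukey adjustment holds the family-wise error near its nominal level", {
  fwe <- vapply(1:500, function(s) {
    tab <- simulate_study_table(24, coefs = list(b_coord = 0, b_gaze = 0,
                                                 b_cg = 0), seed = 2000 + s)
    fit <- suppressWarnings(fit_lmm(tab, y ~ coordination * gaze))
    ct <- suppressMessages(pairwise_contrasts(fit, c("coordination", "gaze")))
    any(ct$p < 0.05)
  }, logical(1))
  expect_lte(mean(fwe), 0.06)
})
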