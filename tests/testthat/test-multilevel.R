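test_that("self-rated health dichotomization follows the good-health cut", {
  expect_equal(dichotomize_srh(c(1, 2, 3, 4, 5)), c(0L, 0L, 0L, 1L, 1L))
  expect_equal(dichotomize_srh(3, cut = 3), 1L)
  expect_equal(dichotomize_srh(c(NA, 5)), c(NA_integer_, 1L))
  expect_error(dichotomize_srh(6), "1..5")
  expect_error(dichotomize_srh(3, cut = 0), "cut")
})

test_that("odds ratios are the exponentiated coefficients", {
  expect_equal(odds_ratio(0), 1)
  expect_equal(odds_ratio(-0.6329), 0.531, tolerance = 5e-4)
  expect_equal(odds_ratio(log(1.842)), 1.842)
  expect_error(odds_ratio(NA_real_), "finite")
})

test_that("baseline fits report complete-case counts and exact OR identity", {
  pop <- small_pop(seed = 31, nv = 25, size = c(15, 25))
  fit <- fit_baseline(pop, "srh_binary", "deaton", nAGQ = 1)
  expect_s3_class(fit, "rd_fit")
  expect_equal(fit$odds_ratios, exp(fit$coefficients))
  expect_equal(fit$n_obs, nrow(pop))
  expect_equal(fit$n_clusters, 25)
  expect_true(is.finite(fit$pseudo_r2))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "odds_ratio") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_obs, fit$n_obs)
  # PADL model only uses the older subsample
  fit_p <- fit_baseline(pop, "padl", "deaton")
  expect_equal(fit_p$n_obs, sum(!is.na(pop$padl)))
  expect_equal(fit_p$n_dropped, sum(is.na(pop$padl)))
})

test_that("relabeling good and bad flips every coefficient and inverts ORs", {
  pop <- small_pop(seed = 32, nv = 30, size = 20)
  fit <- fit_baseline(pop, "srh_binary", "deaton", nAGQ = 1)
  flipped <- pop
  flipped$srh_raw <- 6L - flipped$srh_raw # >=3 on the flipped scale <=> bad
  fit2 <- fit_baseline(flipped, "srh_binary", "deaton", srh_cut = 3, nAGQ = 1)
  expect_equal(fit2$coefficients, -fit$coefficients, tolerance = 1e-3)
  expect_equal(fit2$odds_ratios, 1 / fit$odds_ratios, tolerance = 1e-3)
})

test_that("with no village heterogeneity the linear mixed fit collapses to OLS", {
  # tau = 0 and no mediator path into the outcome, so every village-level
  # signal in the depression score comes through modelled covariates; at this
  # scale the variance estimate hits the boundary and the fit collapses
  pop <- suppressMessages(
    small_pop(seed = 36, nv = 150, size = 20, tau_village = 0,
              gamma_pc_outcome = c(srh = 0.336, cesd = 0, padl = 0.092))
  )
  fit <- suppressMessages(fit_baseline(pop, "cesd", "deaton"))
  expect_lt(fit$random_intercept_variance, 0.02)
  df <- pop
  df$age <- rdhealth:::zscore(df$age)
  df$metotal <- rdhealth:::zscore(df$metotal)
  ols <- lm(as.formula(paste("cesd ~ rd_deaton_z +",
                             paste(default_controls(), collapse = " + "))), df)
  common <- intersect(names(coef(ols)), names(fit$coefficients))
  # at the tau = 0 boundary the ML fixed effects equal the OLS ones
  expect_equal(fit$coefficients[common], coef(ols)[common], tolerance = 1e-6)
  # and within 2 SE regardless
  expect_true(all(abs(fit$coefficients[common] - coef(ols)[common]) <
                    2 * fit$std_errors[common]))
})

test_that("the logistic baseline recovers a generated deprivation odds ratio", {
  # total RD log-odds on good health: -0.56 direct + 0.336 * (-0.2) mediated
  pop <- small_pop(seed = 34, nv = 100, size = 30)
  fit <- fit_baseline(pop, "srh_binary", "deaton", nAGQ = 1)
  or <- fit$odds_ratios[["rd_deaton_z"]]
  expect_gt(or, 0.45)
  expect_lt(or, 0.62)
  expect_gt(fit$random_intercept_variance, 0)
})

test_that("degenerate designs raise explicit errors", {
  pop <- small_pop(seed = 35, nv = 4, size = 8)
  one_village <- pop[pop$village_id == 1, ]
  expect_error(fit_baseline(one_village, "cesd", "deaton"), "2 villages")
  const <- pop
  const$srh_raw <- 5L
  expect_error(fit_baseline(const, "srh_binary", "deaton"), "health classes")
  expect_error(fit_baseline(dplyr::select(pop, -rd_deaton_z), "cesd", "deaton"),
               "rd_deaton_z")
})

test_that("the baseline grid covers every outcome-by-measure cell", {
  pop <- small_pop(seed = 36, nv = 20, size = 15)
  g <- baseline_grid(pop)
  expect_equal(nrow(g), 9)
  expect_equal(sum(!is.na(g$odds_ratio)), 3) # only the logistic rows
  expect_setequal(unique(g$outcome), c("srh_binary", "cesd", "padl"))
})
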