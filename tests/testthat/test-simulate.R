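test_that("identical configs reproduce identical populations", {
  cfg <- sim_config(n_villages = 10, residents_per_village = c(10, 20), seed = 7)
  expect_identical(generate_population(cfg), generate_population(cfg))
  # a different seed produces different draws
  cfg2 <- sim_config(n_villages = 10, residents_per_village = c(10, 20), seed = 8)
  expect_false(identical(generate_population(cfg), generate_population(cfg2)))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_villages = 1), "n_villages")
  expect_error(sim_config(residents_per_village = 1), "residents_per_village")
  expect_error(sim_config(income_log_sd_within = -1), "positive")
  expect_error(sim_config(tau_village = -0.1), "nonnegative")
  expect_error(sim_config(beta_rd_pc = NaN), "finite")
  expect_error(sim_config(noise_sd = c(pc = 0, cesd = 1, padl = 1)), "noise_sd")
  expect_error(sim_config(gamma_pc_outcome = c(srh = 1, cesd = 1)), "srh/cesd/padl")
})

test_that("bounded outcomes never escape their ranges across random configs", {
  set.seed(11)
  for (rep in 1:8) {
    cfg <- sim_config(
      n_villages = 6, residents_per_village = c(5, 15),
      beta_rd_pc = runif(1, -2, 2), beta_interaction_pc = runif(1, -2, 2),
      gamma_rd_outcome = c(srh = runif(1, -3, 3), cesd = runif(1, -5, 5),
                           padl = runif(1, -3, 3)),
      gamma_pc_outcome = c(srh = runif(1, -2, 2), cesd = runif(1, -3, 3),
                           padl = runif(1, -1, 1)),
      tau_village = runif(1, 0, 1), seed = 900 + rep
    )
    pop <- generate_population(cfg)
    expect_true(all(pop$psychological_capital %in% 1:5))
    expect_true(all(pop$srh_raw %in% 1:5))
    expect_true(all(pop$cesd >= 8 & pop$cesd <= 32))
    expect_true(all(pop$padl[!is.na(pop$padl)] %in% 0:7))
    expect_true(all(pop$income > 0))
    expect_true(all(pop$education %in% 0:6))
  }
})

test_that("PADL is missing exactly for the age group at or below the cutoff", {
  pop <- generate_population(sim_config(10, c(10, 20), seed = 3))
  expect_true(all(is.na(pop$padl[pop$age <= 45])))
  expect_false(anyNA(pop$padl[pop$age > 45]))
  pop60 <- generate_population(sim_config(10, c(10, 20), padl_age_cutoff = 60, seed = 3))
  expect_true(all(is.na(pop60$padl[pop60$age <= 60])))
})

test_that("records come sorted by village then person", {
  pop <- generate_population(sim_config(8, c(5, 10), seed = 4))
  expect_false(is.unsorted(pop$village_id))
  expect_false(is.unsorted(order(pop$village_id, pop$person_id)))
})

test_that("a stronger deprivation effect lowers mediator scores among the deprived", {
  mean_pc_deprived <- function(beta) {
    pop <- add_rd_indices(generate_population(
      sim_config(60, 30, beta_rd_pc = beta, seed = 42)
    ))
    top_q <- pop$rd_deaton_z >= quantile(pop$rd_deaton_z, 0.75)
    c(q = mean(pop$psychological_capital[top_q]),
      all = mean(pop$psychological_capital))
  }
  m0 <- mean_pc_deprived(0)
  m1 <- mean_pc_deprived(-0.3)
  m2 <- mean_pc_deprived(-0.6)
  expect_true(m1[["q"]] < m0[["q"]])
  expect_true(m2[["q"]] < m1[["q"]])
  # the overall mean cannot rise when deprivation only subtracts
  expect_lte(m2[["all"]], m0[["all"]] + 0.02)
})

test_that("with all structural effects zero, outcomes decorrelate from deprivation", {
  cfg <- sim_config(
    n_villages = 700, residents_per_village = c(25, 32),
    beta_rd_pc = 0, beta_afi_pc = 0, beta_interaction_pc = 0,
    gamma_pc_outcome = c(srh = 0, cesd = 0, padl = 0),
    gamma_rd_outcome = c(srh = 0, cesd = 0, padl = 0),
    gamma_interaction_outcome = c(srh = 0, cesd = 0, padl = 0),
    control_effects = c(age = 0, gender = 0, education = 0),
    seed = 99
  )
  pop <- add_rd_indices(generate_population(cfg))
  expect_gt(nrow(pop), 15000)
  for (oc in c("psychological_capital", "srh_raw", "cesd")) {
    expect_lt(abs(cor(pop$rd_deaton_z, pop[[oc]])), 0.05)
  }
  cc <- complete.cases(pop$padl)
  expect_lt(abs(cor(pop$rd_deaton_z[cc], pop$padl[cc])), 0.05)
})

test_that("zero village heterogeneity yields near-zero fitted intercept variance", {
  cfg <- sim_config(n_villages = 350, residents_per_village = 30,
                    tau_village = 0,
                    gamma_pc_outcome = c(srh = 0.336, cesd = 0, padl = 0.092),
                    seed = 55)
  pop <- add_rd_indices(generate_population(cfg))
  fit <- fit_baseline(pop, "cesd", "deaton")
  expect_lt(fit$random_intercept_variance, 0.02)
})
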