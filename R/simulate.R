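#' Configuration for the synthetic village-survey generator
#'
#' Bundles the structural parameters of the data-generating process used by
#' [generate_population()]: village-clustered lognormal incomes, a latent
#' psychological-capital mediator driven by standardized relative deprivation
#' (RD) with an RD-by-absolute-family-income (AFI) interaction, and three
#' health outcomes (self-rated health via an ordered-logit latent, CES-D and
#' PADL via rounded-and-clipped linear latents) carrying direct, mediated and
#' interaction paths. Defaults are calibrated to the magnitudes of a rural
#' Chinese household survey: mean log per-capita income 9.28 with total log
#' SD near 0.9 split between and within villages, an RD-to-mediator slope of
#' -0.2, a mediator-to-depression slope of -1.0, and a mediator interaction
#' of 0.235.
#'
#' @param n_villages Number of villages (>= 2).
#' @param residents_per_village Either a single count or a length-2 range
#'   from which village sizes are drawn uniformly. Default 20-40.
#' @param income_log_mean Mean of log per-capita annual household income
#'   (log-yuan).
#' @param income_log_sd_within,income_log_sd_between Within-village and
#'   between-village SDs of log income.
#' @param beta_rd_pc Effect of standardized within-village Deaton RD on the
#'   latent mediator.
#' @param beta_afi_pc Effect of standardized AFI (log income) on the latent
#'   mediator.
#' @param beta_interaction_pc Effect of the centered RD x AFI product on the
#'   latent mediator.
#' @param gamma_pc_outcome,gamma_rd_outcome,gamma_interaction_outcome Named
#'   vectors with elements `srh`, `cesd`, `padl`: the mediator, direct-RD and
#'   RD x AFI interaction effects on each outcome's latent scale (log-odds
#'   for self-rated health).
#' @param control_effects Named vector of control effects (`age`, `gender`,
#'   `education`) applied (on standardized/centered scales) to the mediator
#'   and, with health-consistent signs, to each outcome.
#' @param tau_village SD of the village random intercept, drawn
#'   independently per equation.
#' @param noise_sd Named vector `pc`, `cesd`, `padl` of residual SDs for the
#'   continuous latents (self-rated health uses a standard logistic error).
#' @param pc_intercept,cesd_intercept,padl_intercept Latent-scale intercepts.
#' @param srh_thresholds Four increasing cutpoints on the latent logistic
#'   scale mapping to self-rated health categories 1-5.
#' @param padl_age_cutoff PADL is observed only for age strictly greater
#'   than this (default 45), mirroring the survey instrument.
#' @param confounded_controls If `TRUE`, education is generated with a
#'   positive dependence on household income (for robustness testing);
#'   default `FALSE` generates controls independently of income.
#' @param seed Integer seed; identical configs reproduce identical
#'   populations.
#' @return A `sim_config` list (validated).
#' @examples
#' cfg <- sim_config(n_villages = 5, residents_per_village = 10, seed = 1)
#' @export
sim_config <- function(n_villages = 100L,
                       residents_per_village = c(20L, 40L),
                       income_log_mean = 9.28,
                       income_log_sd_within = 0.80,
                       income_log_sd_between = 0.40,
                       beta_rd_pc = -0.20,
                       beta_afi_pc = 0.10,
                       beta_interaction_pc = 0.235,
                       gamma_pc_outcome = c(srh = 0.336, cesd = -1.0, padl = 0.092),
                       gamma_rd_outcome = c(srh = -0.56, cesd = 1.40, padl = -0.40),
                       gamma_interaction_outcome = c(srh = 0.30, cesd = 0, padl = -0.30),
                       control_effects = c(age = -0.05, gender = 0.05, education = 0.10),
                       tau_village = 0.30,
                       noise_sd = c(pc = 0.55, cesd = 2.7, padl = 0.90),
                       pc_intercept = 3.6,
                       cesd_intercept = 14.5,
                       padl_intercept = 6.6,
                       srh_thresholds = qlogis(c(0.18, 0.36, 0.61, 0.88)),
                       padl_age_cutoff = 45L,
                       confounded_controls = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_villages = as.integer(n_villages),
    residents_per_village = as.integer(residents_per_village),
    income_log_mean = income_log_mean,
    income_log_sd_within = income_log_sd_within,
    income_log_sd_between = income_log_sd_between,
    beta_rd_pc = beta_rd_pc,
    beta_afi_pc = beta_afi_pc,
    beta_interaction_pc = beta_interaction_pc,
    gamma_pc_outcome = gamma_pc_outcome,
    gamma_rd_outcome = gamma_rd_outcome,
    gamma_interaction_outcome = gamma_interaction_outcome,
    control_effects = control_effects,
    tau_village = tau_village,
    noise_sd = noise_sd,
    pc_intercept = pc_intercept,
    cesd_intercept = cesd_intercept,
    padl_intercept = padl_intercept,
    srh_thresholds = srh_thresholds,
    padl_age_cutoff = as.integer(padl_age_cutoff),
    confounded_controls = isTRUE(confounded_controls),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_fields <- c("income_log_mean", "income_log_sd_within", "income_log_sd_between",
                  "beta_rd_pc", "beta_afi_pc", "beta_interaction_pc",
                  "tau_village", "pc_intercept", "cesd_intercept", "padl_intercept")
  for (f in num_fields) assert_finite_scalar(cfg[[f]], f)
  for (f in c("gamma_pc_outcome", "gamma_rd_outcome", "gamma_interaction_outcome")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || any(!is.finite(v)) ||
        !all(c("srh", "cesd", "padl") %in% names(v))) {
      abort(paste0("`", f, "` must be finite and named srh/cesd/padl."))
    }
  }
  if (!is.numeric(cfg$control_effects) || any(!is.finite(cfg$control_effects)) ||
      !all(c("age", "gender", "education") %in% names(cfg$control_effects))) {
    abort("`control_effects` must be finite and named age/gender/education.")
  }
  if (!is.numeric(cfg$noise_sd) || any(!is.finite(cfg$noise_sd)) ||
      any(cfg$noise_sd <= 0) || !all(c("pc", "cesd", "padl") %in% names(cfg$noise_sd))) {
    abort("`noise_sd` must be positive, finite, named pc/cesd/padl.")
  }
  if (cfg$income_log_sd_within <= 0) abort("`income_log_sd_within` must be positive.")
  if (cfg$income_log_sd_between < 0) abort("`income_log_sd_between` must be nonnegative.")
  if (cfg$tau_village < 0) abort("`tau_village` must be nonnegative.")
  if (is.na(cfg$n_villages) || cfg$n_villages < 2L) abort("`n_villages` must be >= 2.")
  rv <- cfg$residents_per_village
  if (any(is.na(rv)) || !length(rv) %in% 1:2 || any(rv < 2L)) {
    abort("`residents_per_village` must be a count or range with minimum >= 2.")
  }
  if (length(rv) == 2L && rv[2] < rv[1]) abort("`residents_per_village` range must be increasing.")
  if (!is.numeric(cfg$srh_thresholds) || length(cfg$srh_thresholds) != 4L ||
      any(!is.finite(cfg$srh_thresholds)) || is.unsorted(cfg$srh_thresholds, strictly = TRUE)) {
    abort("`srh_thresholds` must be 4 strictly increasing finite cutpoints.")
  }
  if (is.na(cfg$seed)) abort("`seed` must be an integer.")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d villages x %s residents, seed %d\n", x$n_villages,
              paste(x$residents_per_village, collapse = "-"), x$seed))
  cat(sprintf("  RD->PC %.3g, PC->(srh,cesd,padl) (%.3g, %.3g, %.3g), RDxAFI->PC %.3g, tau %.3g\n",
              x$beta_rd_pc, x$gamma_pc_outcome["srh"], x$gamma_pc_outcome["cesd"],
              x$gamma_pc_outcome["padl"], x$beta_interaction_pc, x$tau_village))
  invisible(x)
}

#' Generate a synthetic village-clustered survey population
#'
#' Draws a population under the structural model held in a [sim_config()]:
#' village mean log incomes, resident lognormal incomes, standardized
#' within-village Deaton deprivation (computed by the same [rd_deaton()] code
#' used for analysis), a 1-5 psychological-capital mediator, and the three
#' health outcomes. The mediator and the rounded outcomes use dithered
#' rounding (uniform measurement noise before fixed half-integer thresholds)
#' so that the discretized conditional mean stays linear in the structural
#' part and generating coefficients are recoverable on the observed scale;
#' self-rated health arises from an ordered-logit latent whose good/bad
#' dichotomization is exactly a random-intercept logistic model.
#'
#' @param config A [sim_config()].
#' @return A tibble of person records sorted by `(village_id, person_id)`
#'   with columns `person_id`, `village_id`, `income`, `afi` (log income),
#'   the controls (`age`, `gender`, `marital`, `work`, `education`,
#'   `insurance`, `metotal`, `water`, `num_child`, `neighbors`, `strangers`,
#'   `interperson`), `psychological_capital` (1-5), `srh_raw` (1-5), `cesd`
#'   (8-32) and `padl` (0-7, `NA` when `age <= padl_age_cutoff`).
#' @examples
#' pop <- generate_population(sim_config(n_villages = 4, residents_per_village = 8))
#' @export
generate_population <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, as.list(config))
  validate_sim_config(config)
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)

  rv <- config$residents_per_village
  sizes <- if (length(rv) == 1L) rep(rv, config$n_villages) else
    sample(seq(rv[1], rv[2]), config$n_villages, replace = TRUE)
  n <- sum(sizes)
  village_id <- rep(seq_len(config$n_villages), sizes)

  village_mu <- rnorm(config$n_villages, config$income_log_mean, config$income_log_sd_between)
  log_inc <- rnorm(n, village_mu[village_id], config$income_log_sd_within)
  income <- exp(log_inc)
  afi <- log_inc

  # controls; marginals loosely matched to a rural household survey
  age <- pmin(pmax(round(rnorm(n, 46, 19.6)), 9L), 100L)
  gender <- rbinom(n, 1, 0.5)
  marital <- rbinom(n, 1, 0.80)
  work <- rbinom(n, 1, 0.82)
  edu_probs <- c(0.22, 0.28, 0.26, 0.14, 0.05, 0.04, 0.01)
  if (config$confounded_controls) {
    eb <- 0.5 * zscore(afi) + rnorm(n)
    education <- findInterval(eb, qnorm(cumsum(edu_probs)[-7]))
  } else {
    education <- sample(0:6, n, replace = TRUE, prob = edu_probs)
  }
  insurance <- rbinom(n, 1, 0.92)
  metotal <- ifelse(rbinom(n, 1, 0.20) == 1, 0, pmin(pmax(rnorm(n, 6, 2.5), 0), 12.9))
  water <- rbinom(n, 1, 0.62)
  num_child <- pmin(1L + rpois(n, 3.5), 21L)
  neighbors <- pmin(pmax(round(rnorm(n, 6.8, 2.2)), 0L), 10L)
  strangers <- pmin(pmax(round(rnorm(n, 2.1, 2.2)), 0L), 10L)
  interperson <- pmin(pmax(round(rnorm(n, 7.1, 2.0)), 0L), 10L)

  # deprivation within village, standardized over the population
  deaton <- unsplit(lapply(split(income, village_id), rd_deaton), village_id)
  z_rd <- zscore(deaton)
  z_afi <- zscore(afi)
  inter <- center(z_rd) * center(z_afi)

  ce <- config$control_effects
  ctrl <- ce[["age"]] * zscore(age) + ce[["gender"]] * (gender - mean(gender)) +
    ce[["education"]] * zscore(education)

  zeta <- function() rep(rnorm(config$n_villages, 0, config$tau_village), sizes)

  pc_lat <- config$pc_intercept + config$beta_rd_pc * z_rd +
    config$beta_afi_pc * z_afi + config$beta_interaction_pc * inter +
    ctrl + zeta() + rnorm(n, 0, config$noise_sd[["pc"]])
  pc <- as.integer(dither_round(pc_lat, 1L, 5L))
  pc_c <- pc - mean(pc)

  g_rd <- config$gamma_rd_outcome
  g_pc <- config$gamma_pc_outcome
  g_in <- config$gamma_interaction_outcome

  srh_lat <- g_rd[["srh"]] * z_rd + g_pc[["srh"]] * pc_c + g_in[["srh"]] * inter +
    ctrl + zeta() + rlogis(n)
  srh_raw <- as.integer(findInterval(srh_lat, config$srh_thresholds) + 1L)

  cesd_lat <- config$cesd_intercept + g_rd[["cesd"]] * z_rd + g_pc[["cesd"]] * pc_c +
    g_in[["cesd"]] * inter - ctrl + zeta() + rnorm(n, 0, config$noise_sd[["cesd"]])
  cesd <- as.integer(dither_round(cesd_lat, 8L, 32L))

  padl_lat <- config$padl_intercept + g_rd[["padl"]] * z_rd + g_pc[["padl"]] * pc_c +
    g_in[["padl"]] * inter + ctrl + zeta() + rnorm(n, 0, config$noise_sd[["padl"]])
  padl <- as.integer(dither_round(padl_lat, 0L, 7L))
  padl[age <= config$padl_age_cutoff] <- NA_integer_

  tibble::tibble(
    person_id = seq_len(n),
    village_id = village_id,
    income = income,
    afi = afi,
    age = as.integer(age),
    gender = as.integer(gender),
    marital = as.integer(marital),
    work = as.integer(work),
    education = as.integer(education),
    insurance = as.integer(insurance),
    metotal = metotal,
    water = as.integer(water),
    num_child = as.integer(num_child),
    neighbors = as.integer(neighbors),
    strangers = as.integer(strangers),
    interperson = as.integer(interperson),
    psychological_capital = pc,
    srh_raw = srh_raw,
    cesd = cesd,
    padl = padl
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
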