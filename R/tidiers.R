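#' Tidy a baseline model fit
#'
#' @param x An `rd_fit` from [fit_baseline()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, and `odds_ratio` for logistic fits.
#' @export
tidy.rd_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(x$std_errors)
  )
  out$statistic <- out$estimate / out$std_error
  out$p_value <- 2 * pnorm(-abs(out$statistic))
  if (x$family == "logistic") out$odds_ratio <- unname(x$odds_ratios)
  out
}

#' @rdname tidy.rd_fit
#' @export
glance.rd_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_clusters = x$n_clusters, n_dropped = x$n_dropped,
    log_likelihood = x$log_likelihood, pseudo_r2 = x$pseudo_r2,
    pseudo_r2_type = x$pseudo_r2_type,
    random_intercept_variance = x$random_intercept_variance,
    family = x$family, outcome = x$outcome, rd = x$rd
  )
}

#' Tidy a mediation result
#'
#' One row per effect (total, a-path, b-path, direct, indirect) with
#' standard errors and the 95% CI for the direct and indirect effects
#' (Wald or percentile-bootstrap depending on how the object was made).
#'
#' @param x An `rd_mediation`.
#' @param ... Unused.
#' @export
tidy.rd_mediation <- function(x, ...) {
  tibble::tibble(
    term = c("total", "path_a", "path_b", "direct", "indirect"),
    estimate = c(x$total_effect, x$path_a, x$path_b, x$direct_effect,
                 x$indirect_effect),
    std_error = unname(x$se[c("total", "path_a", "path_b", "direct", "indirect")]),
    ci_low = c(NA, NA, NA, x$ci_direct[1], x$ci_indirect[1]),
    ci_high = c(NA, NA, NA, x$ci_direct[2], x$ci_indirect[2]),
    proportion = c(NA, NA, NA, x$proportion_direct, x$proportion_indirect)
  )
}

#' @rdname tidy.rd_mediation
#' @export
glance.rd_mediation <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, rd = x$rd, family = x$family, n_obs = x$n_obs,
    ci_type = x$ci_type, n_bootstrap = x$n_bootstrap,
    proportion_indirect = x$proportion_indirect
  )
}

#' Tidy a moderation result
#'
#' One row per step-4 focal term (deprivation main effect, absolute-income
#' main effect, their interaction).
#'
#' @param x An `rd_moderation`.
#' @param ... Unused.
#' @export
tidy.rd_moderation <- function(x, ...) {
  tibble::tibble(
    term = c("rd", "afi", "rd:afi"),
    estimate = c(x$main_rd, x$main_afi, x$interaction),
    ci_low = c(NA, NA, x$ci_interaction[1]),
    ci_high = c(NA, NA, x$ci_interaction[2]),
    p_value = c(NA, NA, x$p_interaction)
  )
}

#' @rdname tidy.rd_moderation
#' @export
glance.rd_moderation <- function(x, ...) {
  tibble::tibble(
    dependent = x$dependent, rd = x$rd, family = x$family, n_obs = x$n_obs,
    r2_step1 = x$step_r2[1], r2_step2 = x$step_r2[2],
    r2_step3 = x$step_r2[3], r2_step4 = x$step_r2[4],
    interaction = x$interaction, significant = x$significant
  )
}
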