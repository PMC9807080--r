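#' Dichotomize self-rated health
#'
#' Collapses the 1-5 self-rated health scale to good/bad for logistic
#' modelling: 1 ("good") when the raw score is at or above `cut`, else 0
#' ("bad"). The conventional cut treats 4 ("relatively healthy") and 5
#' ("very healthy") as good; the cut-point is configurable because the scale
#' itself does not fix it.
#'
#' @param srh_raw Integer scores in 1-5 (`NA` allowed, passed through).
#' @param cut Smallest raw score counted as good. Default 4.
#' @return Integer 0/1 vector.
#' @examples
#' dichotomize_srh(c(1, 3, 4, 5))
#' dichotomize_srh(3, cut = 3)
#' @export
dichotomize_srh <- function(srh_raw, cut = 4) {
  ok <- is.na(srh_raw) | (srh_raw %in% 1:5)
  if (!all(ok)) abort("`srh_raw` values must lie in 1..5.")
  if (!cut %in% 1:5) abort("`cut` must lie in 1..5.")
  as.integer(srh_raw >= cut)
}

#' Odds ratio from a log-odds coefficient
#'
#' @param coefficient Finite numeric log-odds coefficient(s).
#' @return `exp(coefficient)`.
#' @examples
#' odds_ratio(0)
#' odds_ratio(-0.6329) # ~0.531
#' @export
odds_ratio <- function(coefficient) {
  if (!is.numeric(coefficient) || any(!is.finite(coefficient))) {
    abort("`coefficient` must be finite numeric.")
  }
  exp(coefficient)
}

#' Default control covariate set
#'
#' The individual, family and social controls entering every model: age,
#' gender, marital status, work status, education, medical insurance, log
#' medical expenditure, tap water, household size, and the three trust /
#' relationship scores.
#'
#' @return Character vector of column names.
#' @export
default_controls <- function() {
  c("age", "gender", "marital", "work", "education", "insurance",
    "metotal", "water", "num_child", "neighbors", "strangers", "interperson")
}

# continuous controls that get z-scored before fitting; binary and ordinal
# covariates stay on their raw scales
continuous_controls <- function() c("age", "metotal")

prepare_model_frame <- function(data, outcome, rd, controls, srh_cut = 4,
                                standardize = TRUE, need_mediator = FALSE,
                                need_afi = FALSE) {
  outcome <- match.arg(outcome, c("srh_binary", "cesd", "padl"))
  rd <- match.arg(rd, c("deaton", "podder", "percentile", "yitzhaki"))
  rd_col <- paste0("rd_", rd, if (standardize) "_z" else "")
  if (!rd_col %in% names(data)) {
    abort(paste0("Column `", rd_col, "` not found; run add_rd_indices() first."))
  }
  ycol <- switch(outcome, srh_binary = "srh_raw", cesd = "cesd", padl = "padl")
  need <- c(ycol, rd_col, controls, "village_id",
            if (need_mediator) "psychological_capital", if (need_afi) "afi")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) abort(paste0("Missing column(s): ", paste(miss, collapse = ", "), "."))
  df <- data[stats::complete.cases(data[need]), need, drop = FALSE]
  n_dropped <- nrow(data) - nrow(df)
  if (outcome == "srh_binary") {
    df$.y <- dichotomize_srh(df[[ycol]], cut = srh_cut)
  } else {
    df$.y <- as.numeric(df[[ycol]])
  }
  df$.rd <- as.numeric(df[[rd_col]])
  if (standardize) {
    for (cc in intersect(continuous_controls(), controls)) df[[cc]] <- zscore(df[[cc]])
    if (need_afi) df$.afi <- zscore(df$afi) else df$.afi <- NULL
  } else if (need_afi) df$.afi <- as.numeric(df$afi)
  if (need_mediator) df$.pc <- as.numeric(df$psychological_capital)
  attr(df, "n_dropped") <- n_dropped
  attr(df, "rd_col") <- rd_col
  df
}

#' Fit a two-level baseline health model
#'
#' Fits the random-intercept model `outcome ~ RD + controls + (1 | village)`
#' by maximum likelihood: a mixed logistic regression for dichotomized
#' self-rated health (reported with odds ratios) and a linear mixed model
#' for the CES-D and PADL scores. Continuous predictors are z-scored over
#' the analysis sample (standardize = TRUE); the deprivation variable enters
#' via its `_z` column from [add_rd_indices()]. Rows with missing values on
#' any model variable are dropped (complete-case) and counted.
#'
#' @param data Tibble holding person records plus deprivation columns.
#' @param outcome One of `"srh_binary"`, `"cesd"`, `"padl"`.
#' @param rd Deprivation measure: `"deaton"`, `"podder"` or `"percentile"`.
#' @param controls Control covariates; default [default_controls()].
#' @param srh_cut Good-health cut for [dichotomize_srh()].
#' @param standardize Standardize continuous predictors (default `TRUE`).
#' @param nAGQ Adaptive Gauss-Hermite quadrature points for the logistic
#'   fit (default 5; deterministic).
#' @return An object of class `rd_fit` with elements `coefficients`,
#'   `std_errors`, `odds_ratios` (logistic only), `random_intercept_variance`,
#'   `n_obs`, `n_clusters`, `n_dropped`, `log_likelihood`, `pseudo_r2`
#'   (McFadden for logistic, marginal R-squared for linear), `family`,
#'   `outcome`, `rd`, and the underlying `lme4` fit as `fit`.
#' @examples
#' \donttest{
#' pop <- add_rd_indices(generate_population(sim_config(30, c(15, 25), seed = 2)))
#' fit <- fit_baseline(pop, "cesd", "deaton")
#' tidy(fit)
#' }
#' @export
fit_baseline <- function(data, outcome, rd = "deaton", controls = default_controls(),
                         srh_cut = 4, standardize = TRUE, nAGQ = 5) {
  df <- prepare_model_frame(data, outcome, rd, controls, srh_cut, standardize)
  family <- if (outcome == "srh_binary") "logistic" else "linear"
  n_clusters <- length(unique(df$village_id))
  if (n_clusters < 2L) abort("Degenerate design: need at least 2 villages.")
  if (family == "logistic" && length(unique(df$.y)) < 2L) {
    abort("Degenerate outcome: both health classes must be present.")
  }
  rhs <- paste(c(".rd", controls, "(1 | village_id)"), collapse = " + ")
  fml <- as.formula(paste(".y ~", rhs))
  null_fml <- as.formula(".y ~ 1 + (1 | village_id)")
  if (family == "logistic") {
    fit <- lme4::glmer(fml, data = df, family = binomial(),
                       nAGQ = nAGQ, control = lme4::glmerControl(optimizer = "bobyqa"))
    check_convergence(fit)
    null_fit <- lme4::glmer(null_fml, data = df, family = binomial(), nAGQ = nAGQ,
                            control = lme4::glmerControl(optimizer = "bobyqa"))
    pseudo_r2 <- 1 - as.numeric(logLik(fit)) / as.numeric(logLik(null_fit))
  } else {
    fit <- lme4::lmer(fml, data = df, REML = FALSE)
    check_convergence(fit)
    vf <- var(as.numeric(model.matrix(fit) %*% lme4::fixef(fit)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    tau2 <- vc$vcov[vc$grp == "village_id"]
    sig2 <- vc$vcov[vc$grp == "Residual"]
    pseudo_r2 <- vf / (vf + tau2 + sig2) # marginal R2
  }
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  names(beta) <- names(se) <- rename_rd(names(beta), attr(df, "rd_col"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "village_id"][1]
  structure(list(
    coefficients = beta,
    std_errors = se,
    odds_ratios = if (family == "logistic") odds_ratio(beta) else NULL,
    random_intercept_variance = tau2,
    n_obs = nrow(df),
    n_clusters = n_clusters,
    n_dropped = attr(df, "n_dropped"),
    log_likelihood = as.numeric(logLik(fit)),
    pseudo_r2 = pseudo_r2,
    pseudo_r2_type = if (family == "logistic") "McFadden" else "marginal",
    family = family,
    outcome = outcome,
    rd = attr(df, "rd_col"),
    srh_cut = srh_cut,
    fit = fit
  ), class = "rd_fit")
}

rename_rd <- function(nm, rd_col) {
  nm[nm == ".rd"] <- rd_col
  nm
}

check_convergence <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  code <- fit@optinfo$conv$opt
  if (!is.null(msgs) && any(grepl("failed to converge", msgs, ignore.case = TRUE))) {
    abort(paste0("Model failed to converge: ", paste(msgs, collapse = "; "),
                 " (optimizer code ", code, ")."))
  }
  invisible(fit)
}

#' @export
print.rd_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<rd_fit> %s %s model, RD = %s\n", x$family, x$outcome, x$rd))
  est <- if (x$family == "logistic") x$odds_ratios else x$coefficients
  lab <- if (x$family == "logistic") "OR" else "coef"
  tab <- data.frame(term = names(x$coefficients),
                    est = round(est, digits),
                    se = round(x$std_errors, digits))
  names(tab)[2] <- lab
  print(tab, row.names = FALSE)
  cat(sprintf("N = %d (%d villages, %d rows dropped); log-likelihood = %.1f; %s R2 = %.3f\n",
              x$n_obs, x$n_clusters, x$n_dropped, x$log_likelihood,
              x$pseudo_r2_type, x$pseudo_r2))
  cat(sprintf("Random-intercept variance = %.4f\n", x$random_intercept_variance))
  invisible(x)
}

#' Fit the full baseline grid
#'
#' One baseline model per (deprivation measure, outcome) pair - the 3 x 3
#' layout of the headline results table.
#'
#' @inheritParams fit_baseline
#' @param rd_variables Deprivation measures to sweep.
#' @param outcomes Outcomes to sweep.
#' @return Tibble with list-column `fit` of `rd_fit` objects plus the RD
#'   term's estimate, SE and (for logistic fits) odds ratio.
#' @export
baseline_grid <- function(data, rd_variables = c("deaton", "podder", "percentile"),
                          outcomes = c("srh_binary", "cesd", "padl"),
                          controls = default_controls(), srh_cut = 4) {
  grid <- tidyr::expand_grid(outcome = outcomes, rd = rd_variables)
  grid$fit <- purrr::pmap(grid, function(outcome, rd) {
    fit_baseline(data, outcome = outcome, rd = rd, controls = controls, srh_cut = srh_cut)
  })
  grid$estimate <- purrr::map_dbl(grid$fit, function(f) f$coefficients[[f$rd]])
  grid$std_error <- purrr::map_dbl(grid$fit, function(f) f$std_errors[[f$rd]])
  grid$odds_ratio <- purrr::map_dbl(grid$fit, function(f) {
    if (f$family == "logistic") f$odds_ratios[[f$rd]] else NA_real_
  })
  grid
}
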