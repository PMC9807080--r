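# Build the design pieces for the three mediation regressions once:
#  eq_total : outcome ~ RD + controls          (total effect, alpha1)
#  eq_a     : mediator ~ RD + controls         (a-path, beta1)
#  eq_b     : outcome ~ RD + mediator + controls (direct chi1, b-path chi2)
mediation_design <- function(data, outcome, rd, controls, srh_cut, standardize) {
  df <- prepare_model_frame(data, outcome, rd, controls, srh_cut, standardize,
                            need_mediator = TRUE)
  if (sd(df$.pc) == 0) abort("Degenerate mediator: psychological capital is constant.")
  X0 <- model.matrix(as.formula(paste("~ .rd +", paste(controls, collapse = " + "))), df)
  qr0 <- qr(X0)
  if (qr0$rank < ncol(X0)) {
    drop <- colnames(X0)[qr0$pivot[(qr0$rank + 1):ncol(X0)]]
    abort(paste0("Rank-deficient design; collinear term(s): ",
                 paste(drop, collapse = ", "), "."))
  }
  list(df = df, X0 = X0, X1 = cbind(X0, .pc = df$.pc),
       y = df$.y, m = df$.pc,
       family = if (outcome == "srh_binary") "logistic" else "linear")
}

fit_paths <- function(d, rows = NULL) {
  X0 <- d$X0; X1 <- d$X1; y <- d$y; m <- d$m
  if (!is.null(rows)) {
    X0 <- X0[rows, , drop = FALSE]; X1 <- X1[rows, , drop = FALSE]
    y <- y[rows]; m <- m[rows]
  }
  a_fit <- stats::.lm.fit(X0, m)
  path_a <- a_fit$coefficients[2L]
  if (d$family == "linear") {
    total <- stats::.lm.fit(X0, y)$coefficients[2L]
    bf <- stats::.lm.fit(X1, y)$coefficients
  } else {
    total <- suppressWarnings(
      stats::glm.fit(X0, y, family = binomial())$coefficients)[2L]
    bf <- suppressWarnings(
      stats::glm.fit(X1, y, family = binomial())$coefficients)
  }
  direct <- bf[2L]
  path_b <- bf[length(bf)]
  c(total = unname(total), path_a = unname(path_a),
    direct = unname(direct), path_b = unname(path_b),
    indirect = unname(path_a * path_b))
}

# village-cluster-robust (or iid) vcov for an lm/glm fit
robust_vcov <- function(fit, cluster, se_type) {
  if (se_type == "cluster") sandwich::vcovCL(fit, cluster = cluster) else vcov(fit)
}

#' Stepwise mediation through psychological capital
#'
#' Fits the three regressions of the product-of-coefficients mediation
#' scheme: the total-effect model (outcome on deprivation and controls), the
#' a-path model (mediator on deprivation and controls), and the joint model
#' (outcome on deprivation, mediator and controls) giving the direct effect
#' and the b-path. The indirect effect is the product a x b. The self-rated
#' health outcome uses a logit link, with effects reported on the log-odds
#' scale (where total = direct + indirect holds only approximately, by
#' non-collapsibility); CES-D and PADL use linear regressions, where the
#' identity is exact. The regressions are single-level, matching the
#' mediation equations as specified; standard errors default to
#' village-cluster-robust because the data are clustered.
#'
#' @inheritParams fit_baseline
#' @param se `"cluster"` (village-cluster-robust, default) or `"iid"`.
#' @return An `rd_mediation` object: `total_effect`, `path_a`, `path_b`,
#'   `direct_effect`, `indirect_effect`, their standard errors and Wald 95%
#'   CIs, `proportion_direct` / `proportion_indirect` (percent), `n_obs`,
#'   `outcome`, `rd`, `family`. Bootstrap CIs are added by
#'   [mediate_bootstrap()].
#' @examples
#' \donttest{
#' pop <- add_rd_indices(generate_population(sim_config(30, c(15, 25), seed = 3)))
#' mediate_stepwise(pop, "cesd", "deaton")
#' }
#' @export
mediate_stepwise <- function(data, outcome, rd = "deaton",
                             controls = default_controls(), srh_cut = 4,
                             standardize = TRUE, se = c("cluster", "iid")) {
  se <- match.arg(se)
  d <- mediation_design(data, outcome, rd, controls, srh_cut, standardize)
  est <- fit_paths(d)
  df <- d$df
  ctrl_rhs <- paste(controls, collapse = " + ")
  a_fit <- lm(as.formula(paste(".pc ~ .rd +", ctrl_rhs)), data = df)
  if (d$family == "linear") {
    t_fit <- lm(as.formula(paste(".y ~ .rd +", ctrl_rhs)), data = df)
    b_fit <- lm(as.formula(paste(".y ~ .rd + .pc +", ctrl_rhs)), data = df)
  } else {
    t_fit <- glm(as.formula(paste(".y ~ .rd +", ctrl_rhs)), data = df, family = binomial())
    b_fit <- glm(as.formula(paste(".y ~ .rd + .pc +", ctrl_rhs)), data = df, family = binomial())
  }
  cl <- df$village_id
  se_a <- sqrt(robust_vcov(a_fit, cl, se)[".rd", ".rd"])
  se_t <- sqrt(robust_vcov(t_fit, cl, se)[".rd", ".rd"])
  vb <- robust_vcov(b_fit, cl, se)
  se_d <- sqrt(vb[".rd", ".rd"])
  se_b <- sqrt(vb[".pc", ".pc"])
  # delta-method SE for the product of coefficients
  se_ind <- sqrt(est[["path_b"]]^2 * se_a^2 + est[["path_a"]]^2 * se_b^2)
  z <- qnorm(0.975)
  prop <- effect_proportions(est[["direct"]], est[["indirect"]])
  structure(list(
    outcome = outcome, rd = rd, family = d$family,
    total_effect = est[["total"]], path_a = est[["path_a"]],
    path_b = est[["path_b"]], direct_effect = est[["direct"]],
    indirect_effect = est[["indirect"]],
    se = c(total = se_t, path_a = se_a, path_b = se_b,
           direct = se_d, indirect = se_ind),
    ci_direct = est[["direct"]] + c(-1, 1) * z * se_d,
    ci_indirect = est[["indirect"]] + c(-1, 1) * z * se_ind,
    ci_type = "wald",
    proportion_direct = prop$proportion_direct,
    proportion_indirect = prop$proportion_indirect,
    n_obs = nrow(df), n_dropped = attr(df, "n_dropped"),
    se_type = se, n_bootstrap = 0L, seed = NA_integer_
  ), class = "rd_mediation")
}

#' Bootstrap confidence intervals for mediation effects
#'
#' Nonparametric percentile bootstrap of the direct and indirect effects from
#' [mediate_stepwise()]: resamples rows (or whole villages with
#' `unit = "village"`) with replacement, refits the a-path and joint models,
#' and takes the 2.5th/97.5th percentiles of the replicate distribution.
#' Mediation is declared ("both significant") when neither interval contains
#' zero. Replicates that fail (e.g. a non-converging logistic fit) are
#' redrawn up to `max_retries` times in total before a hard error.
#'
#' @inheritParams mediate_stepwise
#' @param n_boot Bootstrap replicates (>= 200; default 1000).
#' @param seed Integer seed controlling the resampling.
#' @param unit Resampling unit: `"individual"` (default) or `"village"`.
#' @param max_retries Cap on redrawn failing replicates (default 100).
#' @return An `rd_mediation` object whose `ci_direct` / `ci_indirect` are
#'   percentile intervals, with `n_bootstrap`, `seed`, `both_significant`
#'   and the replicate draws in `boot_draws`.
#' @export
mediate_bootstrap <- function(data, outcome, rd = "deaton",
                              controls = default_controls(), n_boot = 1000,
                              seed = 1L, unit = c("individual", "village"),
                              srh_cut = 4, standardize = TRUE,
                              se = c("cluster", "iid"), max_retries = 100) {
  unit <- match.arg(unit)
  if (n_boot < 200) abort("`n_boot` must be at least 200.")
  res <- mediate_stepwise(data, outcome, rd, controls, srh_cut, standardize, se)
  d <- mediation_design(data, outcome, rd, controls, srh_cut, standardize)
  n <- nrow(d$X0)
  vils <- split(seq_len(n), d$df$village_id)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 2,
                  dimnames = list(NULL, c("direct", "indirect")))
  retries <- 0L
  b <- 1L
  while (b <= n_boot) {
    rows <- if (unit == "individual") {
      sample.int(n, n, replace = TRUE)
    } else {
      unlist(vils[sample.int(length(vils), length(vils), replace = TRUE)],
             use.names = FALSE)
    }
    est <- tryCatch(fit_paths(d, rows), error = function(e) NULL)
    if (is.null(est) || any(!is.finite(est[c("direct", "indirect")]))) {
      retries <- retries + 1L
      if (retries > max_retries) {
        abort(sprintf("Bootstrap failed: %d replicates could not be fit (cap %d).",
                      retries, max_retries))
      }
      next
    }
    draws[b, ] <- est[c("direct", "indirect")]
    b <- b + 1L
  }
  if (retries > 0L) {
    inform(sprintf("Bootstrap redrew %d failing replicate(s).", retries))
  }
  res$ci_direct <- unname(quantile(draws[, "direct"], c(0.025, 0.975), type = 7))
  res$ci_indirect <- unname(quantile(draws[, "indirect"], c(0.025, 0.975), type = 7))
  res$ci_type <- "percentile-bootstrap"
  res$n_bootstrap <- as.integer(n_boot)
  res$seed <- as.integer(seed)
  res$boot_unit <- unit
  res$boot_retries <- retries
  res$both_significant <- !interval_contains(res$ci_direct, 0) &&
    !interval_contains(res$ci_indirect, 0)
  res$boot_draws <- tibble::as_tibble(as.data.frame(draws))
  res
}

interval_contains <- function(ci, x) ci[1] <= x && x <= ci[2]

#' Decompose direct and indirect effects into proportions
#'
#' Magnitude-based shares of the combined direct-plus-indirect effect:
#' `proportion_indirect = |indirect| / (|direct| + |indirect|)`, with
#' `proportion_direct` its complement, both reported as percentages. This is
#' the decomposition that reproduces the printed effect-proportion columns
#' from printed effect values.
#'
#' @param direct,indirect Effect estimates (finite; not both zero).
#' @return A one-row tibble with `proportion_direct` and
#'   `proportion_indirect` in percent.
#' @examples
#' effect_proportions(1.405, 0.186) # 88.3 / 11.7
#' @export
effect_proportions <- function(direct, indirect) {
  assert_finite_scalar(direct, "direct")
  assert_finite_scalar(indirect, "indirect")
  denom <- abs(direct) + abs(indirect)
  if (denom == 0) abort("Undefined proportions: both effects are zero.")
  pi_ind <- 100 * abs(indirect) / denom
  tibble::tibble(proportion_direct = 100 - pi_ind, proportion_indirect = pi_ind)
}

#' @export
print.rd_mediation <- function(x, digits = 3, ...) {
  cat(sprintf("<rd_mediation> outcome = %s (%s), RD = %s, N = %d\n",
              x$outcome, x$family, x$rd, x$n_obs))
  cat(sprintf("  total  = %8.*f\n", digits, x$total_effect))
  cat(sprintf("  direct = %8.*f  95%% CI [%.*f, %.*f]  (%s)\n", digits,
              x$direct_effect, digits, x$ci_direct[1], digits, x$ci_direct[2], x$ci_type))
  cat(sprintf("  indirect = %6.*f  95%% CI [%.*f, %.*f]  (a = %.*f, b = %.*f)\n",
              digits, x$indirect_effect, digits, x$ci_indirect[1], digits,
              x$ci_indirect[2], digits, x$path_a, digits, x$path_b))
  cat(sprintf("  effect proportions: direct %.1f%%, indirect %.1f%%\n",
              x$proportion_direct, x$proportion_indirect))
  if (x$n_bootstrap > 0) {
    cat(sprintf("  bootstrap: B = %d, unit = %s, seed = %d, both significant: %s\n",
                x$n_bootstrap, x$boot_unit, x$seed, x$both_significant))
  }
  invisible(x)
}
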