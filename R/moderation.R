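#' Hierarchical moderation by absolute family income
#'
#' Tests whether absolute family income (AFI, log per-capita household
#' income) moderates the deprivation effect, via four nested regressions fit
#' in order: (1) controls only; (2) + deprivation; (3) + AFI; (4) + the
#' product of the mean-centered deprivation and mean-centered AFI terms.
#' Both interacting variables are centered before the product is formed (the
#' symmetric convention), which leaves the interaction slope invariant to
#' location shifts of either variable. The dependent variable may be the
#' mediator (`"pc"`, psychological capital) or any health outcome; a logit
#' link is used for dichotomized self-rated health and linear regression
#' otherwise. Fit statistics per step are R-squared (linear) or McFadden's
#' pseudo-R-squared (logistic), non-decreasing across steps in the linear
#' case. Standard errors default to village-cluster-robust.
#'
#' @inheritParams mediate_stepwise
#' @param dependent `"pc"`, `"srh_binary"`, `"cesd"` or `"padl"`.
#' @param include_mediator For outcome dependents, add psychological capital
#'   to every step so the step-4 interaction probes moderation of the
#'   *direct* deprivation path rather than of the total effect (which also
#'   carries any mediator-transmitted moderation). Default `FALSE`: the
#'   four equations as written, without the mediator. Ignored when
#'   `dependent = "pc"`.
#' @param simple_slopes Also report the deprivation slope at AFI one SD
#'   below/above the mean (default `TRUE`).
#' @return An `rd_moderation` object: `interaction` (step-4 coefficient),
#'   `ci_interaction`, `significant` (5%, two-sided), `main_rd`, `main_afi`,
#'   `step_r2` (length 4), `steps` (list of fits), `simple_slopes`, `n_obs`.
#' @examples
#' \donttest{
#' pop <- add_rd_indices(generate_population(sim_config(30, c(15, 25), seed = 4)))
#' moderate_hierarchical(pop, "pc", "deaton")
#' }
#' @export
moderate_hierarchical <- function(data, dependent, rd = "deaton",
                                  controls = default_controls(), srh_cut = 4,
                                  standardize = TRUE, se = c("cluster", "iid"),
                                  include_mediator = FALSE, simple_slopes = TRUE) {
  se <- match.arg(se)
  dependent <- match.arg(dependent, c("pc", "srh_binary", "cesd", "padl"))
  frame_outcome <- if (dependent == "pc") "cesd" else dependent
  df <- prepare_model_frame(data, frame_outcome, rd, controls, srh_cut,
                            standardize, need_mediator = TRUE, need_afi = TRUE)
  if (dependent == "pc") df$.y <- df$.pc
  family <- if (dependent == "srh_binary") "logistic" else "linear"
  df$.rd_c <- center(df$.rd)
  df$.afi_c <- center(df$.afi)
  df$.inter <- df$.rd_c * df$.afi_c
  if (sd(df$.inter) == 0) abort("Degenerate interaction: RD x AFI product is constant.")
  ctrl_rhs <- paste(controls, collapse = " + ")
  if (include_mediator && dependent != "pc") {
    ctrl_rhs <- paste(ctrl_rhs, "+ .pc")
  } else {
    include_mediator <- FALSE
  }
  rhs <- c(ctrl_rhs,
           paste(ctrl_rhs, "+ .rd"),
           paste(ctrl_rhs, "+ .rd + .afi"),
           paste(ctrl_rhs, "+ .rd + .afi + .inter"))
  fits <- lapply(rhs, function(r) {
    f <- as.formula(paste(".y ~", r))
    if (family == "logistic") glm(f, data = df, family = binomial()) else lm(f, data = df)
  })
  step_r2 <- vapply(fits, function(f) {
    if (family == "logistic") {
      1 - as.numeric(logLik(f)) / as.numeric(logLik(update(f, . ~ 1)))
    } else summary(f)$r.squared
  }, 0)
  f4 <- fits[[4]]
  v4 <- robust_vcov(f4, df$village_id, se)
  b4 <- coef(f4)
  z <- qnorm(0.975)
  eta <- b4[[".inter"]]
  se_eta <- sqrt(v4[".inter", ".inter"])
  ci <- eta + c(-1, 1) * z * se_eta
  se_rd <- sqrt(v4[".rd", ".rd"])
  ci_rd <- b4[[".rd"]] + c(-1, 1) * z * se_rd
  ss <- NULL
  if (simple_slopes) {
    s_afi <- sd(df$.afi_c)
    grad_lo <- grad_hi <- setNames(numeric(length(b4)), names(b4))
    grad_lo[".rd"] <- grad_hi[".rd"] <- 1
    grad_lo[".inter"] <- -s_afi
    grad_hi[".inter"] <- s_afi
    ss <- tibble::tibble(
      afi = c("-1 SD", "+1 SD"),
      slope = c(b4[[".rd"]] - s_afi * eta, b4[[".rd"]] + s_afi * eta),
      std_error = c(sqrt(drop(t(grad_lo) %*% v4 %*% grad_lo)),
                    sqrt(drop(t(grad_hi) %*% v4 %*% grad_hi)))
    )
  }
  structure(list(
    dependent = dependent, rd = rd, family = family,
    interaction = eta, se_interaction = se_eta, ci_interaction = ci,
    p_interaction = 2 * pnorm(-abs(eta / se_eta)),
    significant = abs(eta / se_eta) > z,
    main_rd = b4[[".rd"]], se_main_rd = se_rd, ci_main_rd = ci_rd,
    main_afi = b4[[".afi"]],
    step_r2 = step_r2, steps = fits, simple_slopes = ss,
    include_mediator = include_mediator,
    n_obs = nrow(df), n_dropped = attr(df, "n_dropped"), se_type = se
  ), class = "rd_moderation")
}

#' @export
print.rd_moderation <- function(x, digits = 3, ...) {
  cat(sprintf("<rd_moderation> dependent = %s (%s), RD = %s, N = %d\n",
              x$dependent, x$family, x$rd, x$n_obs))
  cat(sprintf("  RD x AFI = %.*f  95%% CI [%.*f, %.*f]  p = %.3g%s\n",
              digits, x$interaction, digits, x$ci_interaction[1], digits,
              x$ci_interaction[2], x$p_interaction,
              if (x$significant) " *" else ""))
  cat(sprintf("  main RD = %.*f, main AFI = %.*f\n", digits, x$main_rd,
              digits, x$main_afi))
  cat("  step R2:", paste(sprintf("%.4f", x$step_r2), collapse = " -> "), "\n")
  if (!is.null(x$simple_slopes)) {
    cat(sprintf("  RD slope at AFI -1 SD: %.*f, +1 SD: %.*f\n", digits,
                x$simple_slopes$slope[1], digits, x$simple_slopes$slope[2]))
  }
  invisible(x)
}

#' Combine mediation and moderation into a moderated-mediation summary
#'
#' Joins fitted mediation and moderation results computed on the same data
#' and deprivation measure into one table stating which paths (the a-path to
#' the mediator, and the direct path to each outcome) are moderated by
#' absolute income, with a sign interpretation (a moderation coefficient
#' opposing the main deprivation effect attenuates it at higher income).
#' A Holm-adjusted significance column across the tested interactions is
#' appended as an extension beyond the unadjusted 5% convention.
#'
#' @param mediations List of (or a single) `rd_mediation` objects.
#' @param moderations List of (or a single) `rd_moderation` objects.
#' @return A tibble with one row per moderated path: `path`, `dependent`,
#'   `interaction`, `ci_low`, `ci_high`, `significant`,
#'   `significant_holm`, `interpretation`.
#' @export
moderated_mediation_summary <- function(mediations, moderations) {
  if (inherits(mediations, "rd_mediation")) mediations <- list(mediations)
  if (inherits(moderations, "rd_moderation")) moderations <- list(moderations)
  if (length(mediations) == 0 || length(moderations) == 0) {
    abort("Need at least one mediation and one moderation result.")
  }
  rds <- unique(c(purrr::map_chr(mediations, "rd"), purrr::map_chr(moderations, "rd")))
  if (length(rds) != 1) {
    abort(paste0("Inconsistent deprivation measures across results: ",
                 paste(rds, collapse = ", "), "."))
  }
  med_out <- purrr::map_chr(mediations, "outcome")
  rows <- purrr::map_dfr(moderations, function(m) {
    path <- if (m$dependent == "pc") {
      "a-path (RD -> mediator)"
    } else if (isTRUE(m$include_mediator)) {
      paste0("direct path (RD -> ", m$dependent, ")")
    } else {
      paste0("total effect (RD -> ", m$dependent, ")")
    }
    main <- if (m$dependent == "pc") m$main_rd else {
      i <- match(m$dependent, med_out)
      if (!is.na(i)) mediations[[i]]$direct_effect else m$main_rd
    }
    opposing <- sign(m$interaction) != 0 && sign(m$interaction) != sign(main)
    tibble::tibble(
      path = path, dependent = m$dependent,
      interaction = m$interaction,
      ci_low = m$ci_interaction[1], ci_high = m$ci_interaction[2],
      p_value = m$p_interaction,
      significant = m$significant,
      interpretation = if (!m$significant) {
        "no moderation detected"
      } else if (opposing) {
        "higher absolute income attenuates the deprivation effect"
      } else {
        "higher absolute income amplifies the deprivation effect"
      }
    )
  })
  rows$significant_holm <- stats::p.adjust(rows$p_value, method = "holm") < 0.05
  rows
}
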