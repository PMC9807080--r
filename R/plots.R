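#' Forest plot of a baseline fit
#'
#' Coefficients (odds ratios for logistic fits, on a log-scaled axis) with
#' Wald 95% intervals; the intercept is dropped.
#'
#' @param object An `rd_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rd_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  z <- qnorm(0.975)
  td$lo <- td$estimate - z * td$std_error
  td$hi <- td$estimate + z * td$std_error
  ref <- 0
  ylab <- "coefficient"
  if (object$family == "logistic") {
    td$estimate <- exp(td$estimate); td$lo <- exp(td$lo); td$hi <- exp(td$hi)
    ref <- 1
    ylab <- "odds ratio"
  }
  p <- ggplot2::ggplot(td, ggplot2::aes(x = stats::reorder(.data$term, .data$estimate),
                                        y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = ref, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = ylab,
                  title = sprintf("%s model (%s)", object$outcome, object$rd))
  if (object$family == "logistic") p <- p + ggplot2::scale_y_log10()
  p
}

#' Effect plot of a mediation result
#'
#' Direct and indirect effects with their 95% intervals.
#'
#' @param object An `rd_mediation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rd_mediation <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term %in% c("direct", "indirect"), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "effect",
                  title = sprintf("Mediation on %s (%s CIs)", object$outcome,
                                  object$ci_type))
}

#' Simple-slopes plot of a moderation result
#'
#' The fitted deprivation slope at absolute family income one SD below and
#' above its mean, visualising the interaction.
#'
#' @param object An `rd_moderation` (fit with `simple_slopes = TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rd_moderation <- function(object, ...) {
  if (is.null(object$simple_slopes)) {
    abort("Refit with `simple_slopes = TRUE` to plot simple slopes.")
  }
  ss <- object$simple_slopes
  rd_grid <- seq(-2, 2, length.out = 20)
  lines <- purrr::map_dfr(seq_len(nrow(ss)), function(i) {
    tibble::tibble(afi = ss$afi[i], rd = rd_grid, yhat = ss$slope[i] * rd_grid)
  })
  ggplot2::ggplot(lines, ggplot2::aes(x = .data$rd, y = .data$yhat,
                                      colour = .data$afi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "relative deprivation (centered)",
                  y = sprintf("predicted %s (relative)", object$dependent),
                  colour = "absolute income",
                  title = sprintf("RD x AFI interaction = %.3f%s", object$interaction,
                                  if (object$significant) " (p < 0.05)" else ""))
}
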