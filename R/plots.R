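#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` gives each result type its standard display: the BIC trace
#' across model sizes for a subset scan, the cross-validation curve for a
#' lasso fit, the partial-regression scatter with its fitted line, a
#' forest plot for a meta-analysis, and the binned residual trend for the
#' divergence diagnostic.
#'
#' @param object A fitted object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name elevox-plots
NULL

#' @rdname elevox-plots
#' @method autoplot subset_scan
#' @export
autoplot.subset_scan <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$bic)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$optimal), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = "model size", y = "BIC (constants omitted)",
                  title = paste("Best-subset BIC trace:", object$outcome))
}

#' @rdname elevox-plots
#' @method autoplot lasso_cv
#' @export
autoplot.lasso_cv <- function(object, ...) {
  d <- tibble::tibble(lambda = object$lambda, cvm = object$cvm,
                      cvsd = object$cvsd)
  ggplot2::ggplot(d, ggplot2::aes(x = log(.data$lambda), y = .data$cvm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cvm - .data$cvsd,
                                      ymax = .data$cvm + .data$cvsd),
                         fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(c(object$lambda_min,
                                           object$lambda_1se)),
                        linetype = c("dashed", "solid"),
                        colour = "firebrick") +
    ggplot2::labs(x = "log(lambda)", y = "weighted CV error",
                  title = paste("Lasso cross-validation:", object$outcome))
}

#' @rdname elevox-plots
#' @method autoplot partial_fit
#' @export
autoplot.partial_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_resid, y = .data$y_resid)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$weight), size = 1.5) +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         colour = "royalblue") +
    ggplot2::scale_alpha_continuous(range = c(0.2, 0.9), guide = "none") +
    ggplot2::labs(
      x = paste(object$focus, "residual (on remaining covariates)"),
      y = paste(object$outcome, "residual (on covariates without",
                paste0(object$focus, ")")),
      title = sprintf("Partial regression: slope %.2f, partial R2 %.3f",
                      object$slope, object$partial_r2))
}

#' @rdname elevox-plots
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  d <- tidy(object)
  if (!"label" %in% names(d)) d$label <- as.character(seq_len(nrow(d)))
  d$label <- factor(d$label, levels = rev(d$label))
  z <- stats::qnorm(1 - (1 - object$ci_level) / 2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = object$pooled, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$estimate - z * .data$se,
                                         xmax = .data$estimate + z * .data$se),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "stratum estimate", y = NULL,
                  title = sprintf("Fixed-effects pooling: %.2f [%.2f, %.2f], I2 = %.0f%%",
                                  object$pooled, object$conf_low,
                                  object$conf_high, object$i2))
}

#' @rdname elevox-plots
#' @method autoplot divergence_diagnostic
#' @export
autoplot.divergence_diagnostic <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$screen, y = .data$abs_resid)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_step(data = object$trend,
                       ggplot2::aes(x = .data$screen_mid,
                                    y = .data$mean_abs_resid),
                       colour = "royalblue", linewidth = 1) +
    ggplot2::labs(x = object$screen_var, y = "|weighted residual|",
                  title = "Divergence diagnostic (binned mean trend)")
}
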