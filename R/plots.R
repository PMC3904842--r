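#' Plot a deconvolution fit
#'
#' Observed samples, the fitted concentration curve, and the recovered
#' secretory events drawn as needles from zero (their height is the event
#' amount, on the same axis for orientation; amounts and concentrations have
#' different units).
#'
#' @param object A `decon_fit` from [deconvolve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decon_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_segment(
      data = object$pulses,
      ggplot2::aes(x = .data$time_min, xend = .data$time_min,
                   y = 0, yend = .data$amplitude),
      colour = "steelblue", linewidth = 0.4
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$concentration),
                        colour = "firebrick", size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), linewidth = 0.4) +
    ggplot2::labs(
      x = "time (min)",
      y = "serum concentration (assay units) / event amount",
      title = sprintf(
        "%d recovered pulses, R² = %.3f, θ1 = %.4f, θ2 = %.4f",
        object$n_pulses, object$r_squared,
        object$theta_hat$theta1, object$theta_hat$theta2)
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.decon_fit <- function(x, ...) print(autoplot(x, ...))

#' Plot residual whiteness and normality diagnostics
#'
#' Left panel: sample autocorrelation of the fit residuals with the
#' approximate 95% white-noise band. Right panel: normal quantile-quantile
#' plot. Residuals of a well-specified fit stay inside the band and on the
#' reference line.
#'
#' @param object A `residual_diagnostics` from [residual_diagnostics()], or a
#'   `decon_fit` (diagnostics are computed from its residuals).
#' @param max_lag Largest lag when `object` is a `decon_fit`. Default 20.
#' @return A patchwork of two ggplots if the patchwork package is installed,
#'   otherwise a list of the two ggplots.
#' @export
plot_residual_diagnostics <- function(object, max_lag = 20) {
  if (inherits(object, "decon_fit")) {
    object <- residual_diagnostics(object$residuals, max_lag)
  }
  stopifnot(inherits(object, "residual_diagnostics"))
  p_acf <- ggplot2::ggplot(object$acf,
                           ggplot2::aes(x = .data$lag,
                                        y = .data$autocorrelation)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$band,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "lag (samples)", y = "autocorrelation") +
    ggplot2::theme_minimal()
  p_qq <- ggplot2::ggplot(object$qq,
                          ggplot2::aes(x = .data$theoretical,
                                       y = .data$sample)) +
    ggplot2::geom_abline(slope = stats::sd(object$qq$sample),
                         intercept = mean(object$qq$sample),
                         colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "standard normal quantiles", y = "residual quantiles") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(p_acf, p_qq, ncol = 2)
  } else {
    list(acf = p_acf, qq = p_qq)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
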