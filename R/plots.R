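#' Plot model curves
#'
#' @param object An `nsc_curves` tibble from [run_model()].
#' @param what Curve to plot: `"incidence"` (default), `"prevalence"`,
#'   `"N"` or `"r"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nsc_curves
#' @export
autoplot.nsc_curves <- function(object, what = c("incidence", "prevalence",
                                                 "N", "r"), ...) {
  what <- match.arg(what)
  lab <- switch(what,
    incidence = "Incidence (per 100,000 person-years)",
    prevalence = "Prevalence (per 100,000 persons)",
    N = "NSC pool size (cells)",
    r = "Division rate (per cell per year)")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data[[what]])) +
    ggplot2::geom_line(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::labs(x = "Age (years)", y = lab) +
    ggplot2::theme_minimal()
}

#' Plot a calibration against its observed table
#'
#' Fitted incidence curve with the observed per-bin mean rates drawn as
#' horizontal segments over their age spans.
#'
#' @param object An `nsc_fit` from [fit_incidence_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nsc_fit
#' @export
autoplot.nsc_fit <- function(object, ...) {
  obs <- object$residuals
  t_max <- object$settings$grid$t_max
  obs$age_hi_plot <- pmin(obs$age_hi, t_max)
  autoplot(object$curves, "incidence") +
    ggplot2::geom_segment(
      data = obs,
      ggplot2::aes(x = .data$age_lo, xend = .data$age_hi_plot,
                   y = .data$observed, yend = .data$observed),
      colour = "#d7301f", linewidth = 0.8, inherit.aes = FALSE) +
    ggplot2::labs(
      subtitle = sprintf("n_min = %d, k = %.4f /y, S = %.3g",
                         object$n_min, object$k_hat, object$S_hat))
}

#' Plot a bootstrap confidence band
#'
#' @param object An `nsc_bootstrap` from [parametric_bootstrap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nsc_bootstrap
#' @export
autoplot.nsc_bootstrap <- function(object, ...) {
  lvl <- attr(object, "level")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "#a6bddb", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate),
                       colour = "#2c7fb8", linewidth = 0.7) +
    ggplot2::labs(x = "Age (years)",
                  y = "Incidence (per 100,000 person-years)",
                  subtitle = sprintf("%d%% parametric bootstrap band (B = %d)",
                                     round(100 * lvl), attr(object, "B"))) +
    ggplot2::theme_minimal()
}
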