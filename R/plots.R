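# ggplot2 displays for the two result types practitioners plot: the
# Bland-Altman agreement panel and the method-by-characteristic line plot
# of model-estimated compositions.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Scatter of per-pair difference (self minus device) against the
#' mean-of-methods value, with the bias and 95% limits of agreement.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of methods (min/day)",
      y = "Self-reported - device-measured (min/day)"
    ) +
    ggplot2::theme_minimal()
}

#' Line plot of model-estimated compositions across methods
#'
#' One panel per behaviour; each line joins the device-measured to the
#' self-reported estimate for one level of the characteristic. Crossing
#' lines indicate an inverting pattern, approaching lines a converging one.
#'
#' @param estimates Output of [estimate_compositions()] for one
#'   characteristic.
#' @return A ggplot object.
#' @export
plot_estimates <- function(estimates) {
  long <- tidyr::pivot_longer(estimates, dplyr::all_of(BEHAVIOURS),
                              names_to = "behaviour", values_to = "minutes")
  long$behaviour <- factor(long$behaviour, levels = BEHAVIOURS)
  long$method <- factor(long$method, levels = c("device", "self"),
                        labels = c("Device-measured", "Self-reported"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$minutes,
                                     group = .data$level, colour = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~behaviour, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "Estimated time (min/day)",
      colour = unique(estimates$characteristic)
    ) +
    ggplot2::theme_minimal()
}
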