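#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Differences between two methods against their per-cilium means, with
#' the bias and the limits of agreement.
#'
#' @param object A [bland_altman()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid",
      colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "Mean of methods (µm)",
      y = "Difference between methods (µm)",
      title = sprintf("Bias %.2f µm, LoA [%.2f, %.2f]",
        object$bias, object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot cilia_agreement
#' @export
autoplot.cilia_agreement <- function(object, ...) {
  autoplot(object$ba) +
    ggplot2::labs(
      subtitle = sprintf("%s − %s: ICC = %.2f (%s)",
        object$method_a, object$method_b, object$icc, object$icc_label)
    )
}

#' Boxplots of cilium length by population and method
#'
#' @param measurements Tibble with `method`, `length_um`, `classification`.
#' @return A ggplot.
#' @export
plot_length_distributions <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  ggplot2::ggplot(m, ggplot2::aes(
    x = .data$classification, y = .data$length_um,
    fill = .data$classification
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA, coef = Inf) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = NULL, y = "Cilium length (µm)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
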