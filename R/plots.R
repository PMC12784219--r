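#' Plot a leave-one-out error curve
#'
#' Mean reconstruction error per tissue against the number of principal
#' components, the standard diagnostic for choosing the component count.
#'
#' @param object a `pcawarp_loo` tibble from [loo_curve()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pcawarp_loo <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_pcs, y = .data$mean_error,
                                       colour = .data$tissue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of principal components",
                  y = sprintf("mean %s [mm]", gsub("_", " ", object$metric[1])),
                  colour = "tissue") +
    ggplot2::theme_minimal()
}

#' Plot a PC-count / proxy-size sweep
#'
#' @param object a `pcawarp_sweep` tibble from [sweep_table()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pcawarp_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$n_pcs),
                                       y = .data$median_shape_difference,
                                       fill = factor(.data$n_proxy))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(x = "number of principal components",
                  y = "median shape difference [mm]",
                  fill = "proxy points") +
    ggplot2::theme_minimal()
}

#' Plot a shape-error report
#'
#' @param object a `pcawarp_error_report` from [shape_error_report()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pcawarp_error_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tissue, y = .data$median,
                                       fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$median - .data$sd, 0),
                                        ymax = .data$median + .data$sd),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "shape approximation error [mm]") +
    ggplot2::theme_minimal()
}
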