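#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the variance-component wedge
#'
#' Scatter of narrow-sense heritability (or final-level common-environment
#' proportion) against the twin correlations, colour-coded by the number of
#' pathways: the feasible wedge of the basic LP model.
#'
#' @param object An `lp_wedge` tibble from [lp_wedge_grid()].
#' @param quantity `"h2_narrow"` or `"c2_final"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lp_wedge
#' @export
autoplot.lp_wedge <- function(object, quantity = c("h2_narrow", "c2_final"),
                              ...) {
  quantity <- match.arg(quantity)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$r_mz, y = .data$r_dz,
                               colour = .data[[quantity]])) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$k), labeller = "label_both") +
    ggplot2::scale_colour_viridis_c(name = quantity) +
    ggplot2::geom_abline(slope = 0.5, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(x = "MZ correlation", y = "DZ correlation") +
    ggplot2::theme_minimal()
}

#' Plot a phantom-heritability sweep
#'
#' Line plot of phantom heritability against the swept parameter; the
#' correlation panels draw one line per pathway count.
#'
#' @param object An `lp_sweep` tibble from [lp_phantom_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lp_sweep
#' @export
autoplot.lp_sweep <- function(object, ...) {
  xlab <- switch(object$panel[1L],
    mean_offset = "pathway mean offset (sd units)",
    var_diff = "second pathway variance",
    h2_diff = "second pathway heritability",
    "pathway correlation rho"
  )
  p <- if ("k" %in% names(object)) {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$value, y = .data$phantom,
                                 colour = factor(.data$k),
                                 group = factor(.data$k)))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$phantom))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$phantom - 2 * .data$se_phantom,
                   ymax = .data$phantom + 2 * .data$se_phantom),
      size = 0.2
    ) +
    ggplot2::labs(x = xlab, y = "phantom heritability",
                  colour = "pathways k") +
    ggplot2::theme_minimal()
}

#' Plot the three-trait illustration
#'
#' Phantom heritability, narrow-sense heritability and common-variance
#' proportion per trait as a function of pathway count, split by pathway
#' correlation.
#'
#' @param object An `lp_trait_table` tibble from [lp_trait_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lp_trait_table
#' @export
autoplot.lp_trait_table <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("phantom", "h2_narrow", "c2_final"),
                              names_to = "quantity")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$k), y = .data$value,
                               colour = factor(.data$rho),
                               group = factor(.data$rho))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$quantity),
                        ggplot2::vars(.data$trait)) +
    ggplot2::labs(x = "pathways k", y = NULL, colour = "rho") +
    ggplot2::theme_minimal()
}
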