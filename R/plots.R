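#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the optimisation history of a fit
#'
#' Best and mean error norm per generation on a log scale.
#'
#' @param object A `bonecal_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bonecal_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history[, c("generation", "best_err", "mean_err")],
                           cols = c("best_err", "mean_err"),
                           names_to = "which", values_to = "err")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$generation, y = .data$err,
                                  colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Generation", y = expression(err ~ (N^2 / mm^2)),
                  colour = NULL, title = "Genetic-algorithm convergence") +
    ggplot2::theme_minimal()
}

#' Plot a simulated force-deflection response
#'
#' @param object A `bending_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bending_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$deflection_mm, y = .data$force_N)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Deflection (mm)", y = "Force (N)",
                  subtitle = sprintf("k = %.1f N/mm", object$stiffness)) +
    ggplot2::theme_minimal()
}

#' Plot a density-elasticity law over the HU range
#'
#' Draws the continuous modulus curve E(HU) with the per-bin table values
#' overlaid at the bin middles.
#'
#' @param law A [material_law()] or a `bonecal_fit`.
#' @param binning A [hu_binning()].
#' @param hu_range HU interval to draw, defaults to the span of the bin
#'   middles.
#' @return A ggplot object.
#' @export
plot_material_law <- function(law, binning = hu_binning(), hu_range = NULL) {
  if (inherits(law, "bonecal_fit")) law <- law$law
  stopifnot(inherits(law, "material_law"))
  if (is.null(hu_range)) hu_range <- range(binning$middles)
  hu <- seq(hu_range[1], hu_range[2], length.out = 200)
  curve <- tibble::tibble(hu = hu, modulus = young_modulus(hu, law))
  pts <- build_bin_table(binning, law)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$hu, y = .data$modulus)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$hu_middle, y = .data$modulus)) +
    ggplot2::labs(x = "Hounsfield units", y = "Young modulus (MPa)",
                  title = "Calibrated density-elasticity law") +
    ggplot2::theme_minimal()
}
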