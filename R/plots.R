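# Colour scheme shared by the Ramachandran and timeline plots: the usual
# secondary-structure palette (PPII green, beta red, 3-10 yellow, alphaR
# pink, alphaL blue).
state_palette <- c(
  PPII = "#2ca02c", beta = "#d62728", three10 = "#e8c013",
  add_screw = "#b8860b", alphaR = "#ff80c0", alphaL = "#1f77b4",
  zeta = "#9467bd", gamma_prime = "#17becf", other = "grey80"
)

#' Ramachandran density plot with region boxes
#'
#' @param density A [ramachandran_density()] result.
#' @param regions Optional [region_set()] whose boxes are drawn on top.
#' @return A ggplot object.
#' @export
plot_ramachandran <- function(density, regions = NULL) {
  p <- ggplot2::ggplot(density,
                       ggplot2::aes(x = .data$phi_center, y = .data$psi_center,
                                    fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-180, 180),
                         expand = FALSE) +
    ggplot2::labs(x = expression(phi ~ "(deg)"), y = expression(psi ~ "(deg)")) +
    ggplot2::theme_minimal()
  if (!is.null(regions)) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(regions),
      ggplot2::aes(xmin = .data$phi_lo, xmax = .data$phi_hi,
                   ymin = .data$psi_lo, ymax = .data$psi_hi,
                   colour = .data$label),
      inherit.aes = FALSE, fill = NA, linewidth = 0.5
    ) +
      ggplot2::scale_colour_manual(values = state_palette, name = "state")
  }
  p
}

#' Conformation timeline plot
#'
#' One tile per (monomer, time pixel), coloured by conformational state.
#'
#' @param timeline Result of [conformation_timeline()].
#' @return A ggplot object.
#' @export
plot_timeline <- function(timeline) {
  ggplot2::ggplot(timeline,
                  ggplot2::aes(x = .data$pixel, y = .data$residue,
                               fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = state_palette, name = "state") +
    ggplot2::labs(x = "time pixel", y = "monomer") +
    ggplot2::theme_minimal()
}

#' Autocorrelation plot with optional stretched-exponential fit overlay
#'
#' @param object An `acf_series`.
#' @param fit Optional `kww_fit` drawn as a curve over the fit window.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acf_series <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ns, y = .data$C)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ns)", y = "C(t)",
                  title = attr(object, "kind")) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(
      lag_ns = seq(fit$window[1], fit$window[2], length.out = 200)
    )
    grid$C <- fit$A * exp(-(grid$lag_ns / fit$tau_ns)^fit$beta)
    p <- p + ggplot2::geom_line(data = grid, colour = "red",
                                linetype = "dashed")
  }
  p
}

#' Fraction-table bar plot with block-SD error bars
#'
#' @param object A `fraction_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fraction_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$state, y = .data$fraction,
                                       fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fraction - .data$sd,
                   ymax = .data$fraction + .data$sd),
      width = 0.25, na.rm = TRUE
    ) +
    ggplot2::scale_fill_manual(values = state_palette, guide = "none") +
    ggplot2::labs(x = NULL, y = "fraction") +
    ggplot2::theme_minimal()
}
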