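# ggplot2 visualization for curves, spectra and gamma results.

#' Plot a tally curve
#'
#' Dispatches on the curve kind: depth-dose and lateral profiles are drawn
#' as lines with +/- 1 sigma ribbons, spectra as step histograms.
#'
#' @param object A `gridrt_curve` from [pdd_curve()], [lateral_profile()],
#'   [spectrum_table()] or [fluence_at_depths()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gridrt_curve <- function(object, ...) {
  kind <- attr(object, "kind")
  if (kind %in% c("depth", "pdd", "depth_fluence")) {
    ycol <- if ("percent" %in% names(object)) "percent" else "value"
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$depth,
                                              y = .data[[ycol]])) +
      ggplot2::geom_line(color = "steelblue") +
      ggplot2::labs(x = "depth (cm)",
                    y = if (ycol == "percent") "PDD (%)" else "dose (a.u.)")
  } else if (kind == "lateral") {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                              y = .data$value)) +
      ggplot2::geom_line(color = "steelblue") +
      ggplot2::labs(x = "off-axis position (cm)", y = "dose (a.u.)")
  } else {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$energy,
                                              y = .data$fluence)) +
      ggplot2::geom_step(color = "steelblue") +
      ggplot2::labs(x = "energy (MeV)", y = "fluence (1/cm^2)")
  }
  if ("sigma" %in% names(object) && !all(is.na(object$sigma)) &&
      kind %in% c("depth", "lateral")) {
    xcol <- if (kind == "lateral") "position" else "depth"
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(x = .data[[xcol]], ymin = .data$value - .data$sigma,
                   ymax = .data$value + .data$sigma),
      alpha = 0.25, inherit.aes = FALSE)
  }
  p + ggplot2::theme_minimal()
}

#' Plot per-point gamma values
#'
#' @param object A `gridrt_gamma` from [gamma_index_1d()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gridrt_gamma <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$position, y = .data$gamma,
                               color = .data$evaluated)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "steelblue",
                                           `FALSE` = "grey70")) +
    ggplot2::labs(x = "position (cm)", y = expression(gamma),
                  color = "evaluated") +
    ggplot2::theme_minimal()
}
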