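#' Plot methods
#'
#' `autoplot()` methods return ggplot objects: a waveform as a line over
#' time, an ensemble as mean with a +/- 1 sd ribbon, a fit as measured vs
#' simulated pressure overlay, and a sensitivity map or gridded surface as
#' a filled cost contour over the (R1norm, Cnorm) plane.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name windkessel-autoplot
NULL

#' @rdname windkessel-autoplot
#' @export
autoplot.wk_waveform <- function(object, ...) {
  ylab <- if (wf_quantity(object) == "flow") "flow (mL/s)" else
    "pressure (mmHg)"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = ylab)
}

#' @rdname windkessel-autoplot
#' @export
autoplot.wk_nwaveform <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$tau, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time / period",
                  y = sprintf("normalized %s", wf_quantity(object)))
}

#' @rdname windkessel-autoplot
#' @export
autoplot.wk_ensemble <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time / period",
                  y = sprintf("normalized %s (mean +/- sd)",
                              attr(object, "quantity")))
}

#' @rdname windkessel-autoplot
#' @export
autoplot.wk3_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(object$measured), trace = "measured"),
    dplyr::mutate(as_tibble(object$fitted), trace = "simulated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   linetype = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)",
                  linetype = NULL,
                  subtitle = sprintf("L2 error %.2f%%",
                                     object$l2_error_percent))
}

#' @rdname windkessel-autoplot
#' @export
autoplot.wk3_sensitivity <- function(object, ...) {
  autoplot(grid_contour(object))
}

#' @rdname windkessel-autoplot
#' @export
autoplot.wk3_surface <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$r1norm, y = .data$cnorm)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log10(.data$cost))) +
    ggplot2::geom_contour(ggplot2::aes(z = log10(.data$cost)),
                          colour = "white", bins = 8) +
    ggplot2::labs(x = "R1norm", y = "Cnorm",
                  fill = "log10 cost")
}
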