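#' Kymograph of a simulation
#'
#' Space-time raster of the membrane (or cytosolic) concentration.
#'
#' @param object a `polar_sim`.
#' @param species `"m"` or `"c"`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.polar_sim <- function(object, species = c("m", "c"), ...) {
  species <- match.arg(species)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$t,
                                   fill = .data[[species]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = sprintf("%s (1/um)", species)) +
    ggplot2::labs(x = "x (um)", y = "t (s)") +
    ggplot2::theme_minimal()
}

#' Dispersion relation plot
#'
#' Real and imaginary parts of the dominant growth-rate branch against the
#' wavenumber, with the unstable band edge and fastest-growing mode marked.
#'
#' @param object a `dispersion_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.dispersion_result <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("re_sigma", "im_sigma"),
                              names_to = "part", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$q, y = .data$value,
                                          linetype = .data$part)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "q (1/um)", y = "sigma (1/s)") +
    ggplot2::theme_minimal()
  if (!object$empty) {
    p <- p + ggplot2::geom_vline(xintercept = c(object$q_star, object$q_max),
                                 colour = "grey50", linetype = 3)
  }
  p
}

#' Phase-plane trajectory plot
#'
#' The pattern's `(m, c)` trajectory with the reactive nullcline, the
#' best-fit flux-balance line, and the `cL`/`cR` nullcline crossings.
#'
#' @param object a `phase_trajectory`.
#' @param reaction a [reaction_params()] used to draw the nullcline; default
#'   the shipped kinetics.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.phase_trajectory <- function(object, reaction = reaction_params(), ...) {
  pts <- object$points
  mgrid <- seq(0, max(pts$m) * 1.05, length.out = 200)
  nc <- tibble::tibble(m = mgrid, c = nullcline_c(mgrid, reaction))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$m, y = .data$c)) +
    ggplot2::geom_path() +
    ggplot2::geom_line(data = nc, colour = "black", linewidth = 0.3) +
    ggplot2::geom_abline(slope = object$fbs_slope,
                         intercept = object$fbs_intercept,
                         colour = "steelblue", linetype = 2) +
    ggplot2::geom_point(data = object$crossings, colour = "red", size = 1) +
    ggplot2::labs(x = "m (1/um)", y = "c (1/um)") +
    ggplot2::theme_minimal()
}

#' Peak-track plot
#'
#' Unwrapped peak position against time with the fitted propagation line.
#'
#' @param object a `peak_track`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.peak_track <- function(object, ...) {
  ggplot2::ggplot(object$positions,
                  ggplot2::aes(x = .data$t, y = .data$position)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "steelblue") +
    ggplot2::labs(x = "t (s)", y = "peak position (um)") +
    ggplot2::theme_minimal()
}
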