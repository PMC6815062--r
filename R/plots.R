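#' Plot an attenuation spectrum
#'
#' Line plot of the total attenuation and its absorption and scattering
#' components against frequency.
#'
#' @param object An `attenuation_spectrum` from [total_attenuation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot attenuation_spectrum
#' @export
autoplot.attenuation_spectrum <- function(object, ...) {
  units <- attr(object, "units") %||% "db_cm"
  lab <- if (identical(units, "np_cm")) "attenuation (Np/cm)" else "attenuation (dB/cm)"
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::starts_with("alpha_"),
                              names_to = "component", names_prefix = "alpha_",
                              values_to = "alpha")
  ggplot2::ggplot(long, ggplot2::aes(.data$f_mhz, .data$alpha,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (MHz)", y = lab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a size sweep
#'
#' @param object Output of [size_sweep()] with class `size_sweep_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot size_sweep_tbl
#' @export
autoplot.size_sweep_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$f_mhz, .data$alpha_total,
                               colour = factor(round(.data$radius_m * 1e6)))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (MHz)", y = "attenuation (dB/cm)",
                  colour = "radius (um)") +
    ggplot2::theme_minimal()
}

#' Polar plot of a scattering pattern
#'
#' @param pattern Output of [angular_intensity()].
#' @return A ggplot object in polar coordinates; 0 degrees is the forward
#'   direction.
#' @export
plot_polar_pattern <- function(pattern) {
  stopifnot(is.data.frame(pattern),
            all(c("theta", "intensity") %in% names(pattern)))
  ggplot2::ggplot(pattern, ggplot2::aes(.data$theta * 180 / pi,
                                        .data$intensity)) +
    ggplot2::geom_path() +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot attenuation versus porosity
#'
#' @param sweep Output of [porosity_sweep()] with `f` set (possibly
#'   stacked over several radii).
#' @return A ggplot object.
#' @export
plot_porosity_sweep <- function(sweep) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(.data$porosity, .data$alpha_total,
                               colour = factor(round(.data$radius_m * 1e6)))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "porosity", y = "attenuation (dB/cm)",
                  colour = "radius (um)") +
    ggplot2::theme_minimal()
}

#' Plot BUA versus porosity
#'
#' @param sweep Output of [porosity_sweep()] with `f_band` set (possibly
#'   stacked over several radii).
#' @return A ggplot object.
#' @export
plot_bua_sweep <- function(sweep) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(.data$porosity, .data$bua_db_cm_mhz,
                               colour = factor(round(.data$radius_m * 1e6)))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "porosity", y = "BUA (dB/cm/MHz)",
                  colour = "radius (um)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
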