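# Amplitude attenuation unit conversion: 1 Np = 8.6859 dB.
NP_TO_DB <- 8.6859

#' Marrow absorption power law
#'
#' Absorption of the fluid matrix, \eqn{\alpha_1 = a_0 f^n} in dB/cm with
#' `f` in MHz.
#'
#' @param f Frequencies in MHz (non-negative, vectorized).
#' @param material A [fluid_material()] carrying `absorption_prefactor`
#'   and `absorption_exponent`.
#' @return Absorption coefficient(s) in dB/cm.
#' @export
#' @examples
#' marrow <- default_bone_model()$matrix
#' marrow_absorption(1, marrow)   # the prefactor, 3.15 dB/cm
marrow_absorption <- function(f, material) {
  stopifnot(inherits(material, "fluid_material"))
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0)) {
    stop("frequencies must be finite and non-negative", call. = FALSE)
  }
  material$absorption_prefactor * f^material$absorption_exponent
}

#' Scattering component of the attenuation coefficient
#'
#' Attenuation contributed by single scattering from the trabecular
#' cylinders: \eqn{0.5\, n_s\, \gamma^{sca}} with number density
#' \eqn{n_s = \phi/(\pi a^2)}, where the factor 1/2 converts the intensity
#' extinction rate to an amplitude coefficient. The natural unit of the
#' product is Np/m; the default output is dB/cm (1 Np = 8.6859 dB).
#'
#' @param f Frequencies in MHz (positive, vectorized).
#' @param model A [bone_model()].
#' @param units `"db_cm"` (default) or `"np_cm"`.
#' @return Scattering attenuation in the requested units.
#' @export
scattering_attenuation <- function(f, model, units = c("db_cm", "np_cm")) {
  units <- match.arg(units)
  stopifnot(inherits(model, "bone_model"))
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0)) {
    stop("frequencies must be finite and positive", call. = FALSE)
  }
  if (model$bone_volume_fraction == 0) {
    return(rep(0, length(f)))
  }
  np_m <- vapply(f, function(fi) {
    si <- scattering_inputs_from_model(model, frequency_mhz = fi)
    gam <- scattering_cross_section(si, radius = model$radius)
    0.5 * number_density(model) * gam
  }, numeric(1))
  np_cm <- np_m / 100
  if (units == "np_cm") np_cm else np_cm * NP_TO_DB
}

#' Total attenuation spectrum of cancellous bone
#'
#' Composite two-phase attenuation
#' \eqn{\alpha = (1-\phi)\alpha_1 + 0.5\,(\phi/(\pi a^2))\,\gamma^{sca}}:
#' marrow absorption weighted by the marrow volume fraction plus the
#' trabecular scattering term. Absorption inside the trabeculae is
#' neglected (small solid volume fraction, large impedance mismatch).
#'
#' @param f_grid Frequencies in MHz, positive and strictly increasing.
#' @param model A [bone_model()].
#' @param units `"db_cm"` (default) or `"np_cm"`.
#' @return An `attenuation_spectrum`: a tibble with columns `f_mhz`,
#'   `alpha_total`, `alpha_absorption`, `alpha_scattering` (all in
#'   `units`), carrying the model and units as attributes. The components
#'   sum exactly to the total.
#' @seealso [bua()], [crossover_frequency()], [autoplot.attenuation_spectrum()]
#' @export
#' @examples
#' spec <- total_attenuation(seq(0.3, 0.65, length.out = 11), default_bone_model())
#' spec
total_attenuation <- function(f_grid, model, units = c("db_cm", "np_cm")) {
  units <- match.arg(units)
  stopifnot(inherits(model, "bone_model"))
  if (!is.numeric(f_grid) || any(!is.finite(f_grid)) || any(f_grid <= 0)) {
    stop("f_grid must be finite and positive", call. = FALSE)
  }
  if (is.unsorted(f_grid, strictly = TRUE)) {
    stop("f_grid must be strictly increasing", call. = FALSE)
  }
  conv <- if (units == "np_cm") 1 / NP_TO_DB else 1
  alpha_abs <- (1 - model$bone_volume_fraction) *
    marrow_absorption(f_grid, model$matrix) * conv
  alpha_sca <- scattering_attenuation(f_grid, model, units = units)
  out <- tibble::tibble(
    f_mhz = f_grid,
    alpha_total = alpha_abs + alpha_sca,
    alpha_absorption = alpha_abs,
    alpha_scattering = alpha_sca
  )
  class(out) <- c("attenuation_spectrum", class(out))
  attr(out, "model") <- model
  attr(out, "units") <- units
  out
}

#' General two-phase composite attenuation formula
#'
#' The general formula
#' \eqn{\alpha = (1-\phi)\alpha_1 + 0.5\, n_s (\gamma^{sca} + \gamma^{abs})}
#' for a matrix with attenuation \eqn{\alpha_1} containing inclusions of
#' number density \eqn{n_s} with scattering and absorption cross-sections
#' \eqn{\gamma^{sca}}, \eqn{\gamma^{abs}}. [total_attenuation()] is the
#' specialization with \eqn{\gamma^{abs} = 0} and
#' \eqn{n_s = \phi/(\pi a^2)}. All inputs must be supplied in mutually
#' consistent units; the result is returned in the units of
#' `alpha_matrix` (respectively `n_s * gamma`).
#'
#' @param phi Inclusion volume fraction, in `[0, 1]` (vectorized).
#' @param alpha_matrix Matrix attenuation coefficient (non-negative).
#' @param n_s Inclusion number density (non-negative).
#' @param gamma_sca Scattering cross-section of one inclusion (non-negative).
#' @param gamma_abs Absorption cross-section of one inclusion
#'   (non-negative; default 0).
#' @return Total attenuation coefficient(s).
#' @export
general_attenuation <- function(phi, alpha_matrix, n_s, gamma_sca,
                                gamma_abs = 0) {
  vals <- list(phi = phi, alpha_matrix = alpha_matrix, n_s = n_s,
               gamma_sca = gamma_sca, gamma_abs = gamma_abs)
  for (nm in names(vals)) {
    if (!is.numeric(vals[[nm]]) || any(!is.finite(vals[[nm]])) ||
        any(vals[[nm]] < 0)) {
      stop(nm, " must be finite and non-negative", call. = FALSE)
    }
  }
  if (any(phi > 1)) stop("phi must not exceed 1", call. = FALSE)
  (1 - phi) * alpha_matrix + 0.5 * n_s * (gamma_sca + gamma_abs)
}

#' @export
print.attenuation_spectrum <- function(x, ...) {
  units <- attr(x, "units")
  model <- attr(x, "model")
  cat(sprintf("<attenuation_spectrum> %d frequencies, units %s\n",
              nrow(x), units))
  if (!is.null(model)) {
    cat(sprintf("  radius %g um, porosity %g\n",
                model$radius * 1e6, porosity(model)))
  }
  NextMethod()
}
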