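#' Fluid material (marrow matrix)
#'
#' Describes the fluid phase of the composite: the marrow that fills the
#' pore space of cancellous bone. Absorption in the fluid follows the
#' empirical power law \eqn{\alpha_1 = a_0 f^n} with \eqn{f} in MHz and
#' \eqn{\alpha_1} in dB/cm.
#'
#' @param density Mass density in kg/m^3. Must be positive.
#' @param speed Longitudinal sound speed in m/s. Must be positive.
#' @param absorption_prefactor Power-law prefactor \eqn{a_0}, the absorption
#'   in dB/cm at 1 MHz. Must be non-negative.
#' @param absorption_exponent Power-law exponent \eqn{n} (dimensionless,
#'   non-negative).
#'
#' @return An object of class `fluid_material`.
#' @seealso [elastic_material()], [bone_model()], [marrow_absorption()]
#' @export
#' @examples
#' marrow <- fluid_material(900, 1400, absorption_prefactor = 3.15,
#'                          absorption_exponent = 1.15)
#' acoustic_impedance(marrow$density, marrow$speed)
fluid_material <- function(density, speed,
                           absorption_prefactor = 0,
                           absorption_exponent = 0) {
  stopifnot(
    "density must be a single positive number" =
      is.numeric(density) && length(density) == 1L && is.finite(density) && density > 0,
    "speed must be a single positive number" =
      is.numeric(speed) && length(speed) == 1L && is.finite(speed) && speed > 0,
    "absorption_prefactor must be >= 0" =
      is.numeric(absorption_prefactor) && length(absorption_prefactor) == 1L &&
        is.finite(absorption_prefactor) && absorption_prefactor >= 0,
    "absorption_exponent must be >= 0" =
      is.numeric(absorption_exponent) && length(absorption_exponent) == 1L &&
        is.finite(absorption_exponent) && absorption_exponent >= 0
  )
  structure(
    list(
      density = as.numeric(density),
      speed = as.numeric(speed),
      absorption_prefactor = as.numeric(absorption_prefactor),
      absorption_exponent = as.numeric(absorption_exponent)
    ),
    class = "fluid_material"
  )
}

#' Elastic material (solid trabeculae)
#'
#' Describes the solid phase: trabecular bone tissue, treated as an
#' isotropic linear-elastic solid. The shear speed is not stored; it is
#' derived from the longitudinal speed and Poisson ratio by
#' [shear_speed()].
#'
#' @param density Mass density in kg/m^3. Must be positive.
#' @param longitudinal_speed Longitudinal (compressional) wave speed
#'   \eqn{c_1} in m/s. Must be positive.
#' @param poisson_ratio Poisson ratio \eqn{\nu}, in `[0, 0.5)`.
#'
#' @return An object of class `elastic_material`.
#' @seealso [shear_speed()], [bone_model()]
#' @export
#' @examples
#' trabecula <- elastic_material(2000, 3929, 0.24)
#' shear_speed(trabecula)
elastic_material <- function(density, longitudinal_speed, poisson_ratio) {
  stopifnot(
    "density must be a single positive number" =
      is.numeric(density) && length(density) == 1L && is.finite(density) && density > 0,
    "longitudinal_speed must be a single positive number" =
      is.numeric(longitudinal_speed) && length(longitudinal_speed) == 1L &&
        is.finite(longitudinal_speed) && longitudinal_speed > 0,
    "poisson_ratio must lie in [0, 0.5)" =
      is.numeric(poisson_ratio) && length(poisson_ratio) == 1L &&
        is.finite(poisson_ratio) && poisson_ratio >= 0 && poisson_ratio < 0.5
  )
  structure(
    list(
      density = as.numeric(density),
      longitudinal_speed = as.numeric(longitudinal_speed),
      poisson_ratio = as.numeric(poisson_ratio)
    ),
    class = "elastic_material"
  )
}

#' Two-phase model of cancellous bone
#'
#' The complete model configuration: a fluid marrow matrix containing
#' identical solid elastic cylinders (trabeculae) of radius `radius`
#' occupying volume fraction `bone_volume_fraction`. Porosity is
#' `1 - bone_volume_fraction`; the number density of cylinders per unit
#' cross-sectional area is `bone_volume_fraction / (pi * radius^2)`.
#'
#' @param matrix A [fluid_material()] (the marrow).
#' @param trabecula An [elastic_material()] (the trabecular tissue).
#' @param radius Cylinder radius in metres. Must be positive. Note this is
#'   the radius, not the diameter.
#' @param bone_volume_fraction Solid volume fraction, in `[0, 1]`.
#'
#' @return An object of class `bone_model`.
#' @seealso [default_bone_model()], [total_attenuation()]
#' @export
bone_model <- function(matrix, trabecula, radius, bone_volume_fraction) {
  stopifnot(
    "matrix must be a fluid_material" = inherits(matrix, "fluid_material"),
    "trabecula must be an elastic_material" = inherits(trabecula, "elastic_material"),
    "radius must be a single positive number" =
      is.numeric(radius) && length(radius) == 1L && is.finite(radius) && radius > 0,
    "bone_volume_fraction must lie in [0, 1]" =
      is.numeric(bone_volume_fraction) && length(bone_volume_fraction) == 1L &&
        is.finite(bone_volume_fraction) &&
        bone_volume_fraction >= 0 && bone_volume_fraction <= 1
  )
  structure(
    list(
      matrix = matrix,
      trabecula = trabecula,
      radius = as.numeric(radius),
      bone_volume_fraction = as.numeric(bone_volume_fraction)
    ),
    class = "bone_model"
  )
}

#' Reference parameterization of the cancellous bone model
#'
#' Returns the model with the literature material constants used throughout
#' the package's worked examples: trabecular tissue at 2000 kg/m^3,
#' 3929 m/s, Poisson ratio 0.24; marrow at 900 kg/m^3, 1400 m/s with
#' absorption law \eqn{3.15 f^{1.15}} dB/cm; trabecular radius 100 um and
#' bone volume fraction 0.2 (porosity 80%).
#'
#' @return A [bone_model()].
#' @export
#' @examples
#' m <- default_bone_model()
#' porosity(m)
default_bone_model <- function() {
  bone_model(
    matrix = fluid_material(900, 1400,
                            absorption_prefactor = 3.15,
                            absorption_exponent = 1.15),
    trabecula = elastic_material(2000, 3929, 0.24),
    radius = 100e-6,
    bone_volume_fraction = 0.2
  )
}

#' Shear wave speed of an isotropic elastic solid
#'
#' Derives \eqn{c_2 = c_1 \sqrt{(1 - 2\nu) / (2(1 - \nu))}} from the
#' longitudinal speed and Poisson ratio (standard isotropic elasticity).
#' The shear speed vanishes in the incompressible limit \eqn{\nu \to 0.5}.
#'
#' @param material An [elastic_material()].
#' @return Shear speed in m/s.
#' @export
shear_speed <- function(material) {
  stopifnot("material must be an elastic_material" =
              inherits(material, "elastic_material"))
  nu <- material$poisson_ratio
  material$longitudinal_speed * sqrt((1 - 2 * nu) / (2 * (1 - nu)))
}

#' Characteristic acoustic impedance
#'
#' @param density Mass density in kg/m^3 (positive).
#' @param speed Sound speed in m/s (positive).
#' @return Impedance `density * speed` in kg/(s m^2).
#' @export
#' @examples
#' acoustic_impedance(2000, 3929) # trabecular tissue, ~7.9e6
#' acoustic_impedance(900, 1400)  # marrow, ~1.3e6
acoustic_impedance <- function(density, speed) {
  stopifnot(
    "density must be positive" = is.numeric(density) && all(is.finite(density)) && all(density > 0),
    "speed must be positive" = is.numeric(speed) && all(is.finite(speed)) && all(speed > 0)
  )
  density * speed
}

#' Porosity of a bone model
#'
#' @param model A [bone_model()].
#' @return Marrow volume fraction `1 - bone_volume_fraction`.
#' @export
porosity <- function(model) {
  stopifnot(inherits(model, "bone_model"))
  1 - model$bone_volume_fraction
}

#' Number density of trabecular cylinders
#'
#' @param model A [bone_model()].
#' @return Cylinders per unit cross-sectional area,
#'   `bone_volume_fraction / (pi * radius^2)`, in 1/m^2.
#' @export
number_density <- function(model) {
  stopifnot(inherits(model, "bone_model"))
  model$bone_volume_fraction / (pi * model$radius^2)
}

#' Replace the porosity of a bone model
#'
#' Convenience for porosity sweeps: returns the model with
#' `bone_volume_fraction = 1 - porosity`.
#'
#' @param model A [bone_model()].
#' @param porosity New porosity in `[0, 1]`.
#' @return A [bone_model()].
#' @export
set_porosity <- function(model, porosity) {
  stopifnot(inherits(model, "bone_model"),
            is.numeric(porosity), length(porosity) == 1L,
            porosity >= 0, porosity <= 1)
  model$bone_volume_fraction <- 1 - porosity
  model
}

#' @export
print.fluid_material <- function(x, ...) {
  cat("<fluid_material>\n")
  cat(sprintf("  density: %g kg/m^3, speed: %g m/s\n", x$density, x$speed))
  cat(sprintf("  absorption: %g f^%g dB/cm (f in MHz)\n",
              x$absorption_prefactor, x$absorption_exponent))
  invisible(x)
}

#' @export
print.elastic_material <- function(x, ...) {
  cat("<elastic_material>\n")
  cat(sprintf("  density: %g kg/m^3, longitudinal speed: %g m/s, Poisson ratio: %g\n",
              x$density, x$longitudinal_speed, x$poisson_ratio))
  cat(sprintf("  derived shear speed: %g m/s\n", shear_speed(x)))
  invisible(x)
}

#' @export
print.bone_model <- function(x, ...) {
  cat("<bone_model>\n")
  cat(sprintf("  trabecular radius: %g um, bone volume fraction: %g (porosity %g)\n",
              x$radius * 1e6, x$bone_volume_fraction, porosity(x)))
  cat(sprintf("  marrow: %g kg/m^3, %g m/s, absorption %g f^%g dB/cm\n",
              x$matrix$density, x$matrix$speed,
              x$matrix$absorption_prefactor, x$matrix$absorption_exponent))
  cat(sprintf("  trabecula: %g kg/m^3, %g m/s, nu = %g\n",
              x$trabecula$density, x$trabecula$longitudinal_speed,
              x$trabecula$poisson_ratio))
  invisible(x)
}
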