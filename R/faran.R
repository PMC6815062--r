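#' @importFrom rlang .data
NULL

# Bessel J_m and its derivative via the standard recurrence
# J'_m(x) = (J_{m-1}(x) - J_{m+1}(x))/2, J'_0(x) = -J_1(x).
besj <- function(x, m) besselJ(x, m)
besy <- function(x, m) besselY(x, m)
dbesj <- function(x, m) {
  if (m == 0L) -besselJ(x, 1) else (besselJ(x, m - 1) - besselJ(x, m + 1)) / 2
}
dbesy <- function(x, m) {
  if (m == 0L) -besselY(x, 1) else (besselY(x, m - 1) - besselY(x, m + 1)) / 2
}

#' Dimensionless inputs for cylinder scattering
#'
#' Bundles the size parameters and material contrasts that determine the
#' phase shifts: `ka` in the host fluid, `x1 = k1 a` and `x2 = k2 a` for
#' the compressional and shear waves inside the solid cylinder, the
#' fluid-to-solid density ratio, and the solid's Poisson ratio.
#'
#' @param ka Size parameter in the host fluid (positive).
#' @param x1 Compressional size parameter in the solid (positive).
#' @param x2 Shear size parameter in the solid (positive, `x2 > x1`).
#' @param density_ratio Fluid density over solid density (positive).
#' @param poisson_ratio Poisson ratio of the solid, in `[0, 0.5)`.
#'
#' @return An object of class `scattering_inputs`.
#' @seealso [scattering_inputs_from_model()], [phase_shift()],
#'   [scattering_cross_section()]
#' @export
scattering_inputs <- function(ka, x1, x2, density_ratio, poisson_ratio) {
  stopifnot(
    "ka must be a single positive number" =
      is.numeric(ka) && length(ka) == 1L && is.finite(ka) && ka > 0,
    "x1 must be a single positive number" =
      is.numeric(x1) && length(x1) == 1L && is.finite(x1) && x1 > 0,
    "x2 must be a single positive number" =
      is.numeric(x2) && length(x2) == 1L && is.finite(x2) && x2 > 0,
    "x1 must be smaller than x2 (c1 > c2)" = x1 < x2,
    "density_ratio must be positive" =
      is.numeric(density_ratio) && length(density_ratio) == 1L &&
        is.finite(density_ratio) && density_ratio > 0,
    "poisson_ratio must lie in [0, 0.5)" =
      is.numeric(poisson_ratio) && length(poisson_ratio) == 1L &&
        poisson_ratio >= 0 && poisson_ratio < 0.5
  )
  structure(
    list(ka = ka, x1 = x1, x2 = x2,
         density_ratio = density_ratio, poisson_ratio = poisson_ratio),
    class = "scattering_inputs"
  )
}

#' Scattering inputs from a bone model
#'
#' Converts a [bone_model()] plus either a size parameter `ka` or a
#' frequency in MHz into the dimensionless [scattering_inputs()] for the
#' trabecular cylinder embedded in marrow.
#'
#' @param model A [bone_model()].
#' @param ka Size parameter in the marrow. Give exactly one of `ka`,
#'   `frequency_mhz`.
#' @param frequency_mhz Frequency in MHz.
#' @return A [scattering_inputs()].
#' @export
scattering_inputs_from_model <- function(model, ka = NULL, frequency_mhz = NULL) {
  stopifnot(inherits(model, "bone_model"))
  if (is.null(ka) == is.null(frequency_mhz)) {
    stop("give exactly one of `ka` or `frequency_mhz`", call. = FALSE)
  }
  if (is.null(ka)) {
    stopifnot(is.numeric(frequency_mhz), length(frequency_mhz) == 1L, frequency_mhz > 0)
    ka <- 2 * pi * frequency_mhz * 1e6 * model$radius / model$matrix$speed
  }
  c0 <- model$matrix$speed
  c1 <- model$trabecula$longitudinal_speed
  c2 <- shear_speed(model$trabecula)
  scattering_inputs(
    ka = ka,
    x1 = ka * c0 / c1,
    x2 = ka * c0 / c2,
    density_ratio = model$matrix$density / model$trabecula$density,
    poisson_ratio = model$trabecula$poisson_ratio
  )
}

# Boundary-impedance angle of the solid cylinder surface, as a
# numerator/denominator pair (PN, PD) with tan(Phi_m) = PN / PD, so Bessel
# zeros never produce infinities. The solid's shear potential is eliminated
# through the zero-shear-traction condition; (PN, PD) is the resulting
# 2x2-determinant condensation of the in-cylinder boundary conditions.
#
# xi_form = "printed" reproduces, verbatim, a published transcription of the
# boundary angle that carries two typographical errors (an extra "+ m - 1"
# and a doubled tan alpha term); it is retained only so the discrepancy can
# be demonstrated. The default "corrected" form is the classical
# elastic-cylinder result, validated against a first-principles solution of
# the boundary-value problem.
tan_phi_pair <- function(m, inputs, xi_form = c("corrected", "printed")) {
  xi_form <- match.arg(xi_form)
  x1 <- inputs$x1
  x2 <- inputs$x2
  dr <- inputs$density_ratio
  J1 <- besj(x1, m); J1p <- dbesj(x1, m)
  J2 <- besj(x2, m); J2p <- dbesj(x2, m)
  if (xi_form == "printed") {
    ta1 <- -x1 * J1p / J1
    ta2 <- -x2 * J2p / J2
    num <- ta1 / (ta1 + 1) - m^2 / (m^2 + m - 1 - x2^2 / 2 + ta2)
    den <- (m^2 - x2^2 / 2 + 2 * ta1) / (ta1 + 1) -
      m^2 * (ta2 + 1) / (m^2 - x2^2 / 2 + ta2)
    return(c(dr * (-(x2^2 / 2) * num / den), 1))
  }
  if (m == 0L) {
    p_ur <- x1 * J1p
    p_srr <- -x2^2 * J1 - 2 * x1 * J1p
  } else {
    t_c <- -2 * m * (x1 * J1p - J1)
    t_d <- 2 * x2 * J2p + (x2^2 - 2 * m^2) * J2
    p_ur <- x1 * J1p * t_d - m * J2 * t_c
    p_srr <- ((2 * m^2 - x2^2) * J1 - 2 * x1 * J1p) * t_d -
      2 * m * (x2 * J2p - J2) * t_c
  }
  c(dr * x2^2 * p_ur, p_srr)
}

# sin and cos of the phase shift eta_m from the numerator/denominator pair
# N = x J'_m(x) PD + PN J_m(x), M = x N'_m(x) PD + PN N_m(x), with
# tan(eta_m) = -N/M. The overall sign follows the classical convention in
# which the rigid-immovable limit gives eta_m = arctan(-J'_m(x)/N'_m(x))
# and the pressure-release limit gives eta_m = arctan(-J_m(x)/N_m(x)).
# (sin, cos) are defined up to a simultaneous sign flip, which leaves the
# scattered-wave coefficient i sin(eta) exp(i eta) unchanged.
eta_terms <- function(m, inputs, xi_form = "corrected") {
  x <- inputs$ka
  p <- tan_phi_pair(m, inputs, xi_form)
  n_num <- x * dbesj(x, m) * p[2] + p[1] * besj(x, m)
  n_den <- x * dbesy(x, m) * p[2] + p[1] * besy(x, m)
  hyp <- sqrt(n_num^2 + n_den^2)
  if (!is.finite(hyp) || hyp == 0) {
    stop("phase shift evaluation produced a non-finite value", call. = FALSE)
  }
  list(sin = -n_num / hyp, cos = n_den / hyp,
       eta = atan2(-n_num, n_den), sin2 = (n_num / hyp)^2)
}

#' Phase shift of the m-th partial wave
#'
#' Computes the phase-shift angle \eqn{\eta_m} of the m-th cylindrical
#' harmonic of the field scattered by a solid elastic cylinder in a fluid.
#' The scattered-wave coefficient is \eqn{i \sin\eta_m e^{i\eta_m}} and the
#' cross-section involves \eqn{\sin^2\eta_m}; see
#' [scattering_cross_section()].
#'
#' Evaluation is tangent-free: the angle is assembled from
#' numerator/denominator pairs so zeros of the Bessel functions never
#' produce infinities. The angle is reported in \eqn{(-\pi/2, \pi/2]}.
#'
#' @param m Non-negative integer partial-wave order (vectorized).
#' @param inputs A [scattering_inputs()].
#' @param xi_form `"corrected"` (default) uses the classical
#'   elastic-cylinder boundary conditions; `"printed"` reproduces a
#'   published transcription that contains typographical errors and is kept
#'   only for documentation of the discrepancy.
#' @return Phase shift(s) in radians.
#' @export
phase_shift <- function(m, inputs, xi_form = c("corrected", "printed")) {
  xi_form <- match.arg(xi_form)
  stopifnot(inherits(inputs, "scattering_inputs"),
            is.numeric(m), all(m >= 0), all(m == floor(m)))
  vapply(as.integer(m), function(mm) {
    e <- eta_terms(mm, inputs, xi_form)$eta
    # principal branch: eta and eta - pi describe the same partial wave
    if (e > pi / 2) e <- e - pi
    if (e <= -pi / 2) e <- e + pi
    e
  }, numeric(1))
}

# Full truncated series of partial-wave terms. Truncation starts at
# max(10, ceiling(ka) + 12) and extends until the latest term
# eps_m sin^2(eta_m) drops below `tol` times the running sum; hard cap 200.
faran_series <- function(inputs, xi_form = "corrected", tol = 1e-12,
                         m_cap = 200L) {
  m_min <- max(10L, as.integer(ceiling(inputs$ka)) + 12L)
  s <- numeric(0); cs <- numeric(0); sin2 <- numeric(0)
  running <- 0
  m <- 0L
  repeat {
    t <- eta_terms(m, inputs, xi_form)
    s <- c(s, t$sin); cs <- c(cs, t$cos); sin2 <- c(sin2, t$sin2)
    eps <- if (m == 0L) 1 else 2
    term <- eps * t$sin2
    running <- running + term
    if (m >= m_min && term < tol * running) break
    if (m >= m_cap) {
      rlang::abort(
        paste0("partial-wave series failed to converge within m_max = ", m_cap),
        class = "boneatten_convergence_error")
    }
    m <- m + 1L
  }
  list(m = 0:m, sin = s, cos = cs, sin2 = sin2, m_max = m)
}

#' Phase-shift series for a scattering configuration
#'
#' Returns all phase shifts kept by the automatic series truncation, one
#' row per partial-wave order.
#'
#' @inheritParams phase_shift
#' @return A tibble with columns `m`, `eta` (radians), `sin2` and the
#'   truncation order as attribute `m_max`.
#' @export
phase_shift_series <- function(inputs, xi_form = c("corrected", "printed")) {
  xi_form <- match.arg(xi_form)
  stopifnot(inherits(inputs, "scattering_inputs"))
  ser <- faran_series(inputs, xi_form)
  out <- tibble::tibble(
    m = ser$m,
    eta = atan2(ser$sin, ser$cos),
    sin2 = ser$sin2
  )
  attr(out, "m_max") <- ser$m_max
  attr(out, "ka") <- inputs$ka
  out
}

#' Scattering cross-section per unit length of an elastic cylinder
#'
#' Total scattered power per unit incident intensity and unit cylinder
#' length, \eqn{\gamma^{sca} = (4a/ka)\sum_m \epsilon_m \sin^2\eta_m}
#' with Neumann factors \eqn{\epsilon_0 = 1}, \eqn{\epsilon_m = 2}.
#'
#' @inheritParams phase_shift
#' @param radius Cylinder radius in metres (consistent with
#'   `inputs$ka`).
#' @return Cross-section per unit length, in metres.
#' @export
#' @examples
#' m <- default_bone_model()
#' si <- scattering_inputs_from_model(m, ka = 0.5)
#' scattering_cross_section(si, radius = m$radius)
scattering_cross_section <- function(inputs, radius,
                                     xi_form = c("corrected", "printed")) {
  xi_form <- match.arg(xi_form)
  stopifnot(inherits(inputs, "scattering_inputs"),
            is.numeric(radius), length(radius) == 1L, radius > 0)
  ser <- faran_series(inputs, xi_form)
  eps <- c(1, rep(2, ser$m_max))
  (4 * radius / inputs$ka) * sum(eps * ser$sin2)
}

#' Angular pattern of the scattered intensity
#'
#' Far-field scattered intensity versus angle,
#' \eqn{I(\theta) \propto |\sum_m \epsilon_m \sin\eta_m e^{i\eta_m}
#' \cos(m\theta)|^2}. `theta = 0` is the forward (incident propagation)
#' direction; the pattern is symmetric about the incidence axis.
#'
#' @param theta_grid Angles in radians (non-empty).
#' @param inputs A [scattering_inputs()].
#' @param normalize If `TRUE` (default) the pattern is scaled to unit
#'   maximum; if `FALSE` the raw squared modulus is returned, which
#'   recovers the cross-section by quadrature:
#'   \eqn{\gamma^{sca} = (2a/(\pi\, ka)) \int_0^{2\pi} I(\theta)\, d\theta}.
#' @return A tibble with columns `theta` and `intensity`.
#' @export
angular_intensity <- function(theta_grid, inputs, normalize = TRUE) {
  stopifnot(inherits(inputs, "scattering_inputs"))
  if (!is.numeric(theta_grid) || length(theta_grid) == 0L) {
    stop("theta_grid must be a non-empty numeric vector", call. = FALSE)
  }
  ser <- faran_series(inputs)
  eps <- c(1, rep(2, ser$m_max))
  # f(theta) = sum eps sin(eta) [cos(eta) + i sin(eta)] cos(m theta)
  re_coef <- eps * ser$sin * ser$cos
  im_coef <- eps * ser$sin * ser$sin
  basis <- outer(theta_grid, ser$m, function(th, mm) cos(mm * th))
  intensity <- (basis %*% re_coef)^2 + (basis %*% im_coef)^2
  intensity <- drop(intensity)
  if (normalize) intensity <- intensity / max(intensity)
  tibble::tibble(theta = theta_grid, intensity = intensity)
}

#' Long-wavelength (Rayleigh) limit of the cross-section
#'
#' Rigid-cylinder limiting form \eqn{(3/4)\pi^2 (ka)^3 a}, valid for
#' \eqn{ka \ll 1}. This is the limit for an immovable rigid cylinder; the
#' full elastic solution converges to a smaller, material-dependent
#' coefficient, so this function serves as an order-of-magnitude limit
#' check rather than a substitute for [scattering_cross_section()].
#'
#' @param ka Size parameter (non-negative; intended `ka << 1`).
#' @param radius Cylinder radius in metres.
#' @return Approximate cross-section per unit length, metres.
#' @export
rayleigh_limit <- function(ka, radius) {
  stopifnot(is.numeric(ka), all(ka >= 0),
            is.numeric(radius), all(radius > 0))
  0.75 * pi^2 * ka^3 * radius
}

#' Scattering cross-section over a grid of size parameters
#'
#' Evaluates \eqn{\gamma^{sca}} for the trabecular cylinder of a bone model
#' across a `ka` grid, together with a max-normalized column for plotting.
#'
#' @param ka_grid Strictly positive, strictly increasing size parameters.
#' @param model A [bone_model()].
#' @return A tibble with columns `ka`, `gamma_sca` (m) and
#'   `gamma_normalized` (unit maximum); the normalization is recorded in
#'   attribute `normalization`.
#' @export
gamma_vs_ka <- function(ka_grid, model) {
  stopifnot(inherits(model, "bone_model"),
            is.numeric(ka_grid), length(ka_grid) >= 1L, all(ka_grid > 0))
  if (is.unsorted(ka_grid, strictly = TRUE)) {
    stop("ka_grid must be strictly increasing", call. = FALSE)
  }
  gam <- vapply(ka_grid, function(k) {
    scattering_cross_section(scattering_inputs_from_model(model, ka = k),
                             radius = model$radius)
  }, numeric(1))
  out <- tibble::tibble(
    ka = ka_grid,
    gamma_sca = gam,
    gamma_normalized = gam / max(gam)
  )
  attr(out, "normalization") <- "maximum of gamma_sca over the grid"
  out
}
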