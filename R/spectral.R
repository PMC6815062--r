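#' Broadband ultrasound attenuation (BUA) slope
#'
#' Ordinary least-squares line fitted to the total attenuation versus
#' frequency over the BUA band. The slope, in dB/cm/MHz, is the broadband
#' ultrasound attenuation used clinically to assess bone status; the band
#' default 0.3--0.65 MHz is the range over which cancellous-bone
#' attenuation is quasi-linear in frequency.
#'
#' @param spectrum An `attenuation_spectrum` from [total_attenuation()],
#'   or any data frame with columns `f_mhz` and `alpha_total`.
#' @param f_band Fit interval in MHz, length 2. The spectrum must contain
#'   at least 5 points inside the band.
#' @return A `linear_fit` object with elements `slope`, `intercept`,
#'   `r_squared`, `f_band`, `n`. Methods: [tidy()][generics::tidy],
#'   [glance()][generics::glance], `print`.
#' @export
#' @examples
#' spec <- total_attenuation(seq(0.3, 0.65, length.out = 50), default_bone_model())
#' bua(spec)
bua <- function(spectrum, f_band = c(0.3, 0.65)) {
  stopifnot(is.data.frame(spectrum),
            all(c("f_mhz", "alpha_total") %in% names(spectrum)),
            is.numeric(f_band), length(f_band) == 2L, f_band[1] < f_band[2])
  keep <- spectrum$f_mhz >= f_band[1] & spectrum$f_mhz <= f_band[2]
  if (sum(keep) < 5L) {
    stop("spectrum must cover the fit band with at least 5 points; got ",
         sum(keep), call. = FALSE)
  }
  d <- spectrum[keep, ]
  fit <- stats::lm(alpha_total ~ f_mhz, data = d)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      f_band = range(d$f_mhz),
      n = nrow(d)
    ),
    class = "linear_fit"
  )
}

#' Power-law fit of an attenuation component
#'
#' Least-squares fit of `log(values)` against `log(f_grid)`; the slope is
#' the power-law exponent and `exp(intercept)` the prefactor (value at
#' 1 MHz). Used to characterize the frequency dependence of the
#' scattering component, which approaches the cubic Rayleigh behaviour at
#' long wavelengths.
#'
#' @param f_grid Frequencies in MHz (positive, at least 5 points).
#' @param values Attenuation values in dB/cm (strictly positive).
#' @return A `powerlaw_fit` object with elements `prefactor`, `exponent`,
#'   `r_squared`. Methods: [tidy()][generics::tidy],
#'   [glance()][generics::glance], `print`.
#' @export
#' @examples
#' f <- seq(0.3, 0.65, length.out = 50)
#' powerlaw_exponent(f, 2 * f^3)   # recovers exponent 3
powerlaw_exponent <- function(f_grid, values) {
  stopifnot(is.numeric(f_grid), is.numeric(values),
            length(f_grid) == length(values))
  if (length(f_grid) < 5L) {
    stop("need at least 5 points for a power-law fit", call. = FALSE)
  }
  if (any(f_grid <= 0) || any(values <= 0)) {
    stop("power-law fit requires strictly positive frequencies and values",
         call. = FALSE)
  }
  fit <- stats::lm(log(values) ~ log(f_grid))
  structure(
    list(
      prefactor = exp(unname(stats::coef(fit)[1])),
      exponent = unname(stats::coef(fit)[2]),
      r_squared = suppressWarnings(summary(fit)$r.squared)
    ),
    class = "powerlaw_fit"
  )
}

#' Absorption/scattering crossover frequency
#'
#' Finds the frequency at which the scattering component of the
#' attenuation equals the absorption component. Below the crossover,
#' absorption dominates; above it, scattering (growing roughly as
#' frequency cubed) takes over. The difference is scanned on a 100-point
#' grid for sign changes and each bracket is refined by bisection
#' ([stats::uniroot()]) to 1e-4 MHz.
#'
#' @param model A [bone_model()].
#' @param f_range Search interval in MHz, length 2.
#' @return A one-row tibble with columns `crossover_mhz` (`NA` when the
#'   components do not cross on `f_range`), `status` (`"ok"`,
#'   `"no_crossover"` or `"multiple"`) and `n_crossings`. With multiple
#'   sign changes the lowest crossing is reported.
#' @export
#' @examples
#' crossover_frequency(default_bone_model())
crossover_frequency <- function(model, f_range = c(0.1, 1.5)) {
  stopifnot(inherits(model, "bone_model"),
            is.numeric(f_range), length(f_range) == 2L,
            all(f_range > 0), f_range[1] < f_range[2])
  diff_fun <- function(f) {
    scattering_attenuation(f, model) -
      (1 - model$bone_volume_fraction) * marrow_absorption(f, model$matrix)
  }
  grid <- seq(f_range[1], f_range[2], length.out = 100L)
  d <- vapply(grid, diff_fun, numeric(1))
  sgn <- sign(d)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(d == 0)
  if (length(flips) == 0L && length(exact) == 0L) {
    return(tibble::tibble(crossover_mhz = NA_real_,
                          status = "no_crossover", n_crossings = 0L))
  }
  roots <- c(
    grid[exact],
    vapply(flips, function(i) {
      stats::uniroot(diff_fun, lower = grid[i], upper = grid[i + 1],
                     tol = 1e-4)$root
    }, numeric(1))
  )
  roots <- sort(roots)
  tibble::tibble(
    crossover_mhz = roots[1],
    status = if (length(roots) > 1L) "multiple" else "ok",
    n_crossings = length(roots)
  )
}

#' Attenuation or BUA as a function of porosity
#'
#' Sweeps the porosity of the model and evaluates either the attenuation
#' components at a single frequency (`f`), or the BUA slope over a band
#' (`f_band`, fitted on `n_points` frequencies). At fixed frequency the
#' total attenuation is exactly affine in porosity, since both the
#' absorption weight and the scatterer number density are linear in the
#' volume fractions.
#'
#' @param model A [bone_model()] supplying materials and radius.
#' @param porosities Porosity values in `[0, 1]`, increasing.
#' @param f Frequency in MHz for a fixed-frequency sweep. Give exactly one
#'   of `f`, `f_band`.
#' @param f_band Band in MHz for a BUA sweep.
#' @param n_points Number of frequencies used per BUA fit (default 50).
#' @return A tibble with one row per porosity: columns `porosity`,
#'   `radius_m`, and either `f_mhz`, `alpha_total`, `alpha_absorption`,
#'   `alpha_scattering` or `bua_db_cm_mhz`, `r_squared`.
#' @export
#' @examples
#' porosity_sweep(default_bone_model(), c(0.7, 0.8, 0.9), f = 0.5)
porosity_sweep <- function(model, porosities, f = NULL, f_band = NULL,
                           n_points = 50L) {
  stopifnot(inherits(model, "bone_model"),
            is.numeric(porosities), length(porosities) >= 1L,
            all(porosities >= 0), all(porosities <= 1))
  if (is.unsorted(porosities)) {
    stop("porosities must be increasing", call. = FALSE)
  }
  if (is.null(f) == is.null(f_band)) {
    stop("give exactly one of `f` or `f_band`", call. = FALSE)
  }
  if (!is.null(f)) {
    purrr::map_dfr(porosities, function(p) {
      spec <- total_attenuation(f, set_porosity(model, p))
      dplyr::mutate(tibble::as_tibble(spec),
                    porosity = p, radius_m = model$radius,
                    .before = 1)
    })
  } else {
    f_grid <- seq(f_band[1], f_band[2], length.out = n_points)
    purrr::map_dfr(porosities, function(p) {
      fit <- bua(total_attenuation(f_grid, set_porosity(model, p)),
                 f_band = f_band)
      tibble::tibble(porosity = p, radius_m = model$radius,
                     bua_db_cm_mhz = fit$slope, r_squared = fit$r_squared)
    })
  }
}

#' Attenuation spectra for several trabecular radii
#'
#' Evaluates the attenuation spectrum for each radius and stacks the
#' results in long format, enabling the size-dependence overlays
#' (attenuation is larger for larger trabecular radius at fixed porosity).
#'
#' @param model A [bone_model()]; its radius is replaced by each value in
#'   `radii`.
#' @param radii Cylinder radii in metres (positive).
#' @param f_grid Frequencies in MHz, positive increasing.
#' @return A long tibble with columns `radius_m`, `f_mhz`, `alpha_total`,
#'   `alpha_absorption`, `alpha_scattering`.
#' @export
#' @examples
#' size_sweep(default_bone_model(), c(70, 100, 150) * 1e-6, c(0.4, 0.5))
size_sweep <- function(model, radii, f_grid) {
  stopifnot(inherits(model, "bone_model"),
            is.numeric(radii), all(radii > 0))
  out <- purrr::map_dfr(radii, function(a) {
    m <- model
    m$radius <- a
    dplyr::mutate(tibble::as_tibble(total_attenuation(f_grid, m)),
                  radius_m = a, .before = 1)
  })
  class(out) <- c("size_sweep_tbl", class(out))
  out
}

# ---- broom-style methods and printing ----------------------------------

#' @export
print.linear_fit <- function(x, ...) {
  cat("<linear_fit>\n")
  cat(sprintf("  slope: %.4f dB/cm/MHz, intercept: %.4f dB/cm\n",
              x$slope, x$intercept))
  cat(sprintf("  r^2: %.5f on %d points in [%.3g, %.3g] MHz\n",
              x$r_squared, x$n, x$f_band[1], x$f_band[2]))
  invisible(x)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("<powerlaw_fit>\n")
  cat(sprintf("  prefactor: %.4f dB/cm at 1 MHz, exponent: %.4f\n",
              x$prefactor, x$exponent))
  cat(sprintf("  r^2 (log-log): %.5f\n", x$r_squared))
  invisible(x)
}

#' Tidy a BUA linear fit
#'
#' @param x A `linear_fit` from [bua()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' Glance at a BUA linear fit
#'
#' @inheritParams tidy.linear_fit
#' @return A one-row tibble with `r_squared`, `n`, `f_min`, `f_max`.
#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n,
                 f_min = x$f_band[1], f_max = x$f_band[2])
}

#' Tidy a power-law fit
#'
#' @param x A `powerlaw_fit` from [powerlaw_exponent()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy powerlaw_fit
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(
    term = c("prefactor", "exponent"),
    estimate = c(x$prefactor, x$exponent)
  )
}

#' Glance at a power-law fit
#'
#' @inheritParams tidy.powerlaw_fit
#' @return A one-row tibble with `r_squared`.
#' @method glance powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
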