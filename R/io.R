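#' Write a self-describing CSV table
#'
#' Writes a data frame as CSV preceded by `#`-prefixed metadata lines
#' recording the full parameterization of the run. Numeric columns are
#' formatted with 10 significant digits, so identical inputs always
#' produce byte-identical files.
#'
#' @param rows A data frame (may have zero rows).
#' @param path Output path.
#' @param metadata Named list or character vector written as
#'   `# name: value` header lines.
#' @return `path`, invisibly.
#' @export
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_table(data.frame(x = pi), p, metadata = list(units = "db_cm"))
#' readLines(p)
write_table <- function(rows, path, metadata = list()) {
  stopifnot(is.data.frame(rows))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  header <- c(
    sprintf("# boneatten %s", as.character(utils::packageVersion("boneatten"))),
    vapply(names(metadata), function(nm) {
      sprintf("# %s: %s", nm, paste(format(metadata[[nm]], digits = 10),
                                    collapse = " "))
    }, character(1))
  )
  fmt <- function(col) {
    if (is.numeric(col)) formatC(col, digits = 10, format = "g") else as.character(col)
  }
  body <- paste(names(rows), collapse = ",")
  if (nrow(rows) > 0L) {
    cols <- lapply(rows, fmt)
    body <- c(body, do.call(paste, c(cols, sep = ",")))
  }
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to a CSV produced by [write_table()].
#' @return A tibble; the `#` metadata lines are returned in attribute
#'   `metadata`.
#' @export
read_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  out <- utils::read.csv(text = paste(body, collapse = "\n"))
  out <- tibble::as_tibble(out)
  attr(out, "metadata") <- meta
  out
}

model_metadata <- function(model, ...) {
  c(list(
    radius_um = model$radius * 1e6,
    bone_volume_fraction = model$bone_volume_fraction,
    porosity = porosity(model),
    marrow = sprintf("%g kg/m^3, %g m/s, %g f^%g dB/cm",
                     model$matrix$density, model$matrix$speed,
                     model$matrix$absorption_prefactor,
                     model$matrix$absorption_exponent),
    trabecula = sprintf("%g kg/m^3, %g m/s, nu %g",
                        model$trabecula$density,
                        model$trabecula$longitudinal_speed,
                        model$trabecula$poisson_ratio)
  ), list(...))
}

#' Regenerate the package's reference figure tables
#'
#' Writes the data tables behind the model's headline figures into
#' `outdir`: polar scattering patterns at wavelengths \eqn{8\pi a} and
#' \eqn{4\pi a} (`fig1a`, `fig1b`), the cross-section versus `ka`
#' (`fig1c`), attenuation spectra for several trabecular radii (`fig2`),
#' the absorption and scattering components over the BUA band (`fig3`),
#' and attenuation and BUA versus porosity (`fig4`, `fig5`). Output is
#' deterministic across runs. When `render_plots = TRUE`, companion PDF
#' plots are written with ggplot2.
#'
#' @param outdir Output directory (created if needed).
#' @param model Base [bone_model()]; defaults to [default_bone_model()].
#' @param render_plots Also write PDF renderings (default `FALSE`).
#' @return Character vector of the files written, invisibly.
#' @export
regenerate_figures <- function(outdir, model = default_bone_model(),
                               render_plots = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, rows, ...) {
    p <- file.path(outdir, paste0(name, ".csv"))
    write_table(rows, p, metadata = model_metadata(model, ...))
    files <<- c(files, p)
  }

  # polar patterns: lambda = 8 pi a (ka = 0.25) and 4 pi a (ka = 0.5)
  theta <- seq(0, 2 * pi, by = pi / 180)
  for (it in list(list("fig1a", 0.25), list("fig1b", 0.5))) {
    si <- scattering_inputs_from_model(model, ka = it[[2]])
    pat <- angular_intensity(theta, si)
    emit(it[[1]],
         data.frame(theta_deg = theta * 180 / pi,
                    intensity_normalized = pat$intensity),
         ka = it[[2]])
  }

  # cross-section versus ka
  ka_grid <- seq(0.05, 3, length.out = 60)
  emit("fig1c", as.data.frame(gamma_vs_ka(ka_grid, model)),
       normalization = "max")

  # spectra by trabecular radius
  f_grid <- seq(0.1, 1.5, length.out = 29)
  radii <- c(40, 70, 100, 150) * 1e-6
  fig2 <- size_sweep(model, radii, f_grid)
  emit("fig2", as.data.frame(fig2), radii_um = radii * 1e6)

  # absorption and scattering components over the BUA band
  fig3 <- total_attenuation(seq(0.3, 0.65, length.out = 50), model)
  emit("fig3", as.data.frame(fig3), band_mhz = c(0.3, 0.65))

  # attenuation and BUA versus porosity
  poro <- seq(0.7, 0.95, by = 0.025)
  fig4 <- purrr::map_dfr(c(70, 100, 150) * 1e-6, function(a) {
    m <- model
    m$radius <- a
    porosity_sweep(m, poro, f = 0.5)
  })
  emit("fig4", as.data.frame(fig4), f_mhz = 0.5)
  fig5 <- purrr::map_dfr(c(70, 100, 150) * 1e-6, function(a) {
    m <- model
    m$radius <- a
    porosity_sweep(m, poro, f_band = c(0.3, 0.65), n_points = 12L)
  })
  emit("fig5", as.data.frame(fig5), band_mhz = c(0.3, 0.65))

  if (render_plots) {
    pdfs <- list(
      fig2 = ggplot2::autoplot(fig2),
      fig3 = ggplot2::autoplot(fig3),
      fig4 = plot_porosity_sweep(fig4),
      fig5 = plot_bua_sweep(fig5)
    )
    for (nm in names(pdfs)) {
      p <- file.path(outdir, paste0(nm, ".pdf"))
      ggplot2::ggsave(p, pdfs[[nm]], width = 6, height = 4)
      files <- c(files, p)
    }
  }
  invisible(files)
}
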