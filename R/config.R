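CONFIG_SCHEMA_VERSION <- "1"

config_allowed_keys <- list(
  top = c("schema_version", "matrix", "trabecula", "radius",
          "bone_volume_fraction", "units"),
  matrix = c("density", "speed", "absorption_prefactor", "absorption_exponent"),
  trabecula = c("density", "longitudinal_speed", "poisson_ratio")
)

#' Load and validate a run configuration
#'
#' Reads a JSON configuration whose keys mirror the model fields
#' (`matrix`, `trabecula`, `radius`, `bone_volume_fraction`, optional
#' `units` and `schema_version`). Missing keys are filled from
#' [default_bone_model()]; an empty file yields the all-defaults
#' configuration. Unknown keys are rejected, and all physical bounds are
#' enforced at load time with every violation reported at once.
#'
#' @param path Path to a JSON file.
#' @return A `run_config`: list with elements `model` (a [bone_model()]),
#'   `units`, `schema_version` and `source`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (nzchar(trimws(txt))) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else {
    list()
  }
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)

  problems <- character(0)
  unknown <- setdiff(names(raw), config_allowed_keys$top)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  for (sub in c("matrix", "trabecula")) {
    if (!is.null(raw[[sub]])) {
      bad <- setdiff(names(raw[[sub]]), config_allowed_keys[[sub]])
      if (length(bad)) {
        problems <- c(problems, paste0("unknown key(s) under '", sub, "': ",
                                       paste(bad, collapse = ", ")))
      }
    }
  }
  if (length(problems)) {
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }

  def <- default_bone_model()
  get_or <- function(lst, key, default) {
    if (is.null(lst[[key]])) default else lst[[key]]
  }
  mat <- raw$matrix %||% list()
  tra <- raw$trabecula %||% list()
  fields <- list(
    matrix_density = get_or(mat, "density", def$matrix$density),
    matrix_speed = get_or(mat, "speed", def$matrix$speed),
    absorption_prefactor = get_or(mat, "absorption_prefactor",
                                  def$matrix$absorption_prefactor),
    absorption_exponent = get_or(mat, "absorption_exponent",
                                 def$matrix$absorption_exponent),
    trabecula_density = get_or(tra, "density", def$trabecula$density),
    longitudinal_speed = get_or(tra, "longitudinal_speed",
                                def$trabecula$longitudinal_speed),
    poisson_ratio = get_or(tra, "poisson_ratio", def$trabecula$poisson_ratio),
    radius = get_or(raw, "radius", def$radius),
    bone_volume_fraction = get_or(raw, "bone_volume_fraction",
                                  def$bone_volume_fraction)
  )
  checks <- list(
    matrix_density = c("matrix density must be > 0", fields$matrix_density > 0),
    matrix_speed = c("matrix speed must be > 0", fields$matrix_speed > 0),
    absorption_prefactor = c("absorption_prefactor must be >= 0",
                             fields$absorption_prefactor >= 0),
    absorption_exponent = c("absorption_exponent must be >= 0",
                            fields$absorption_exponent >= 0),
    trabecula_density = c("trabecula density must be > 0",
                          fields$trabecula_density > 0),
    longitudinal_speed = c("longitudinal_speed must be > 0",
                           fields$longitudinal_speed > 0),
    poisson_ratio = c("poisson_ratio must lie in [0, 0.5)",
                      fields$poisson_ratio >= 0 && fields$poisson_ratio < 0.5),
    radius = c("radius must be > 0", fields$radius > 0),
    bone_volume_fraction = c("bone_volume_fraction must lie in [0, 1]",
                             fields$bone_volume_fraction >= 0 &&
                               fields$bone_volume_fraction <= 1)
  )
  for (nm in names(checks)) {
    if (!is.numeric(fields[[nm]]) || length(fields[[nm]]) != 1L ||
        !is.finite(fields[[nm]]) || !as.logical(checks[[nm]][2])) {
      problems <- c(problems, paste0(nm, ": ", checks[[nm]][1],
                                     " (got ", fields[[nm]], ")"))
    }
  }
  units <- get_or(raw, "units", "db_cm")
  if (!units %in% c("db_cm", "np_cm")) {
    problems <- c(problems, "units must be 'db_cm' or 'np_cm'")
  }
  if (length(problems)) {
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }

  model <- bone_model(
    matrix = fluid_material(fields$matrix_density, fields$matrix_speed,
                            fields$absorption_prefactor,
                            fields$absorption_exponent),
    trabecula = elastic_material(fields$trabecula_density,
                                 fields$longitudinal_speed,
                                 fields$poisson_ratio),
    radius = fields$radius,
    bone_volume_fraction = fields$bone_volume_fraction
  )
  structure(
    list(model = model, units = units,
         schema_version = as.character(get_or(raw, "schema_version",
                                              CONFIG_SCHEMA_VERSION)),
         source = normalizePath(path)),
    class = "run_config"
  )
}

#' Write a run configuration to JSON
#'
#' Serializes a `run_config` (or a bare [bone_model()]) so that
#' [load_config()] round-trips it bit-identically.
#'
#' @param config A `run_config` or [bone_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "bone_model")) {
    config <- list(model = config, units = "db_cm",
                   schema_version = CONFIG_SCHEMA_VERSION)
  }
  m <- config$model
  out <- list(
    schema_version = config$schema_version,
    matrix = m$matrix[c("density", "speed", "absorption_prefactor",
                        "absorption_exponent")],
    trabecula = m$trabecula[c("density", "longitudinal_speed",
                              "poisson_ratio")],
    radius = m$radius,
    bone_volume_fraction = m$bone_volume_fraction,
    units = config$units
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
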