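#' Default model configuration
#'
#' The anchor parameter set used throughout the parameter studies: an
#' inclined tube (`phi = pi/6`) carrying a stenosis (length 0.2, entry gap
#' 0.2) followed by a post-stenotic dilatation (length 0.2, gap 0.6), body
#' forces `M = 2`, `F = 0.3`, flux `Q = 0.1`, plug radius `r0 = 0.2`, both
#' lesion heights 0.1 unless a sweep varies them.
#'
#' @return A nested list understood by [read_config()]'s consumers.
#' @export
default_config <- function() {
  list(
    geometry = list(
      segments = list(
        list(kind = "stenosis", height = 0.1, length = 0.2, gap = 0.2),
        list(kind = "dilatation", height = 0.1, length = 0.2, gap = 0.6)
      ),
      domain_length = "auto"
    ),
    casson = list(plug_radius = 0.2),
    forces = list(M = 2.0, F = 0.3, phi = pi / 6),
    flux = 0.1,
    mode = "paper",
    quadrature_points = 2001L,
    radial_probe = 0.2
  )
}

# Angles may be written as expressions over pi ("pi/6"); anything else in a
# numeric slot must be a number.
parse_numeric <- function(x, what = "value") {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x) && grepl("^[0-9pi/*+. ()-]+$", x)) {
    val <- tryCatch(eval(parse(text = x), envir = list(pi = pi),
                         enclos = baseenv()),
                    error = function(e) NULL)
    if (is.numeric(val) && length(val) == 1L) return(as.numeric(val))
  }
  stop(sprintf("cannot interpret %s: %s", what, deparse(x)))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a model configuration file
#'
#' YAML or JSON, chosen by file extension. Missing keys fall back to
#' [default_config()]; the `segments` list, when present, replaces the
#' default geometry wholesale.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  )
  cfg <- merge_config(default_config(), raw)
  cfg$forces$phi <- parse_numeric(cfg$forces$phi, "forces.phi")
  cfg
}

#' Write a configuration file
#'
#' Inverse of [read_config()]; parsing then re-serializing is idempotent.
#'
#' @param config A configuration list.
#' @param path Destination path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(config, path, precision = 15L),
    json = jsonlite::write_json(config, path, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    stop("unsupported config format: .", ext)
  )
  invisible(path)
}

#' Build the vessel geometry described by a configuration
#'
#' @param config A configuration list (see [default_config()]).
#' @return A [vessel_geometry()].
#' @export
config_geometry <- function(config) {
  segs <- lapply(config$geometry$segments, function(s) {
    abnormal_segment(parse_numeric(s$height, "segment height"),
                     parse_numeric(s$length, "segment length"),
                     parse_numeric(s$gap, "segment gap"),
                     kind = s$kind)
  })
  dl <- config$geometry$domain_length
  if (!identical(dl, "auto")) dl <- parse_numeric(dl, "domain_length")
  vessel_geometry(segs, domain_length = dl)
}

#' Build the body-force field described by a configuration
#'
#' @param config A configuration list.
#' @return A [force_field()].
#' @export
config_forces <- function(config) {
  f <- config$forces
  force_field(M = parse_numeric(f$M, "forces.M"),
              F_grav = parse_numeric(f$F, "forces.F"),
              phi = parse_numeric(f$phi, "forces.phi"))
}

#' Plug-core radius described by a configuration
#'
#' Either `casson.plug_radius` directly, or `casson.yield_stress` together
#' with `casson.nominal_pressure_gradient`, converted through
#' [plug_radius_from_yield()].
#'
#' @param config A configuration list.
#' @return The plug radius `r0`.
#' @export
config_plug_radius <- function(config) {
  cs <- config$casson
  if (!is.null(cs$plug_radius))
    return(parse_numeric(cs$plug_radius, "casson.plug_radius"))
  if (!is.null(cs$yield_stress)) {
    if (is.null(cs$nominal_pressure_gradient))
      stop("casson.yield_stress requires casson.nominal_pressure_gradient")
    return(plug_radius_from_yield(
      parse_numeric(cs$yield_stress, "casson.yield_stress"),
      parse_numeric(cs$nominal_pressure_gradient,
                    "casson.nominal_pressure_gradient")))
  }
  stop("config must provide casson.plug_radius or casson.yield_stress")
}

#' Solve the configured model
#'
#' One-call entry point: builds the geometry, forces and plug radius from a
#' configuration and returns the full [axial_solution()].
#'
#' @param config A configuration list or a path to a config file.
#' @param ... Passed on to [axial_solution()] (e.g. `station`).
#' @return An `axial_solution` object.
#' @export
solve_config <- function(config, ...) {
  if (is.character(config)) config <- read_config(config)
  axial_solution(parse_numeric(config$flux, "flux"),
                 config_geometry(config),
                 config_plug_radius(config),
                 config_forces(config),
                 mode = config$mode,
                 quadrature_points = as.integer(config$quadrature_points),
                 ...)
}
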