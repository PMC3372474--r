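#' Read and run a structured configuration file
#'
#' A run configuration is a YAML document with sections `geometry`
#' (shape, diameter_mm, height_mm, tissue_thickness_mm, placement,
#' resolution, grading_ratio), `materials` (any [material_set()] field),
#' `porous` (tissue_phi, skeleton_phi), `boundary` (U_inlet, U_bottom,
#' T_value, bottom_mode), `irradiance` (I, alpha, t_on) and `solver`
#' (any [solver_config()] field).  Missing entries fall back to the
#' package defaults, so a minimal file states only the geometry and
#' irradiance.
#'
#' @param path Path to a YAML run configuration.
#' @return A list with the assembled `case` ([fvm_case()]) and `config`
#'   ([solver_config()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geo <- cfg$geometry
  if (is.null(geo)) stop("configuration needs a geometry section")
  coral <- coral_shape(
    geo$shape %||% "hemisphere",
    radius = (geo$diameter_mm %||% 35) / 2000,
    height = if (!is.null(geo$height_mm)) geo$height_mm / 1000 else NULL,
    tissue_thickness = (geo$tissue_thickness_mm %||% 1) / 1000)
  domain <- chamber_domain(
    length = (cfg$domain$length_mm %||% 250) / 1000,
    width = (cfg$domain$width_mm %||% 50) / 1000,
    height = (cfg$domain$height_mm %||% 100) / 1000)
  mesh <- build_mesh(domain, coral,
                     resolution = as.integer(geo$resolution %||% c(48, 26, 26)),
                     grading_ratio = geo$grading_ratio %||% 1.2,
                     placement = geo$placement %||% 0.4)
  mat <- do.call(material_set, cfg$materials %||% list())
  d <- 2 * coral$radius
  porous <- list(
    tissue = porous_zone_spec(cfg$porous$tissue_phi %||% 0.05, d),
    skeleton = porous_zone_spec(cfg$porous$skeleton_phi %||% 0.5, d))
  bargs <- cfg$boundary %||% list()
  bcs <- do.call(boundary_set, bargs)
  ir <- cfg$irradiance %||% list()
  src <- irradiance_source(ir$I %||% 0, ir$alpha %||% 0.2,
                           t_on = ir$t_on %||% 0)
  sargs <- cfg$solver %||% list()
  solver <- do.call(solver_config, sargs)
  list(case = fvm_case(mesh, mat, porous, bcs, src), config = solver)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a time series or table to CSV
#'
#' @param x Data frame (e.g. a transient `series` or a sweep table).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_series_csv <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE)
  invisible(file)
}
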