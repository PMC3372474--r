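#' Validation species presets
#'
#' The five coral colonies of the validation experiments, read from the
#' preset file shipped with the package: colony shape and dimensions,
#' measured (or assumed) skeletal porosities, chamber Reynolds numbers,
#' illumination onsets for the dark-light runs, and the low/high-flow
#' model warming values at 600 W/m^2.
#'
#' @return A named list of `species_preset` objects.
#' @export
make_presets <- function() {
  path <- system.file("extdata", "species.yaml", package = "coraltherm",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  out <- lapply(raw$species, function(s) {
    coral <- coral_shape(s$shape, radius = s$diameter_mm / 2000,
                         height = if (!is.null(s$height_mm))
                           s$height_mm / 1000 else NULL)
    structure(
      list(name = s$name, coral = coral, scenario = s$scenario,
           porosity = s$porosity, porosity_assumed = isTRUE(s$porosity_assumed),
           alpha_range = unlist(raw$alpha_range),
           Re_low = s$Re_low,
           Re_high = if (is.null(s$Re_high)) NA_real_ else s$Re_high,
           t_on_s = if (is.null(s$t_on_s)) NA_real_ else s$t_on_s,
           table6_model_low_K = if (is.null(s$table6_model_low_K))
             NA_real_ else s$table6_model_low_K,
           table6_model_high_K = if (is.null(s$table6_model_high_K))
             NA_real_ else s$table6_model_high_K,
           desk_resolution = as.integer(unlist(s$desk_resolution))),
      class = "species_preset")
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' @exportS3Method
print.species_preset <- function(x, ...) {
  cat(sprintf("<species_preset> %s: %s d = %.0f mm, phi = %.3f%s\n",
              x$name, x$coral$kind, 2000 * x$coral$radius, x$porosity,
              if (x$porosity_assumed) " (assumed)" else ""))
  invisible(x)
}

#' Chamber Reynolds number
#'
#' `Re = U d / nu` with `d` the colony (or branch) diameter.
#'
#' @param U Flow speed, m/s.
#' @param d Diameter, m.
#' @param nu Kinematic viscosity, m^2/s (seawater at 26 C by default).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(U, d, nu = material_set()$nu) {
  stopifnot(U >= 0, d > 0, nu > 0)
  U * d / nu
}

# Shared scaffolding: build the case for a species at a given flow.
preset_case <- function(preset, I, alpha, U_inlet, t_on = 0,
                        resolution = NULL, materials = material_set(),
                        tissue_phi = 0.05, domain = chamber_domain()) {
  stopifnot(inherits(preset, "species_preset"))
  if (is.null(resolution)) resolution <- preset$desk_resolution
  coral <- preset$coral
  d <- 2 * coral$radius
  mesh <- build_mesh(domain, coral, resolution)
  porous <- list(tissue = porous_zone_spec(tissue_phi, d),
                 skeleton = porous_zone_spec(preset$porosity, d))
  fvm_case(mesh, materials,
           porous = porous,
           bcs = boundary_set(U_inlet = U_inlet),
           source = irradiance_source(I, alpha, t_on = t_on))
}

#' Steady irradiance sweep
#'
#' Replicates the outdoor steady-state irradiance series: steady solves
#' at each irradiance level under constant inflow, a warming table, and
#' the linear irradiance-response fit.  The flow field is solved once
#' and reused (irradiance does not alter the flow).
#'
#' @param preset A [make_presets()] entry (or any `species_preset`).
#' @param I_list Irradiances, W/m^2 (default four levels over 500-950).
#' @param U Inlet flow, m/s.
#' @param alpha Tissue absorptivity (default mid-range 0.2).
#' @param resolution Optional mesh triple; defaults to the preset's.
#' @param config A [solver_config()].
#' @return List: `table` (data frame `I`, `dT`, `dT_max`), `fit` (a
#'   [irradiance_response()] result, `NULL` when fewer than 3 levels),
#'   `alpha`, `flow_converged`.
#' @export
run_steady_sweep <- function(preset, I_list = c(500, 650, 800, 950),
                             U = 0.002, alpha = 0.2, resolution = NULL,
                             config = solver_config()) {
  case <- preset_case(preset, I = I_list[1], alpha = alpha, U_inlet = U,
                      resolution = resolution)
  flow <- solve_flow(case, config)
  sys <- energy_system(case, flow$state)
  psv <- energy_psolve(case, sys)
  rows <- lapply(I_list, function(I) {
    case$source <- irradiance_source(I, alpha)
    st <- solve_energy_steady(case, flow$state, system = sys,
                              psolve = psv, scheme = config$energy_scheme)
    w <- surface_warming(st, case)
    data.frame(I = I, dT = unname(w["mean"]), dT_max = unname(w["max"]))
  })
  tab <- do.call(rbind, rows)
  fit <- if (length(unique(tab$I)) >= 3)
    irradiance_response(data.frame(I = tab$I, dT = tab$dT)) else NULL
  list(table = tab, fit = fit, alpha = alpha,
       flow_converged = flow$converged)
}

#' Dark-light transient run
#'
#' Replicates a dark-light shift: flow spin-up in darkness, illumination
#' switched on at the species' onset time, implicit-Euler warming until
#' `duration` seconds after the onset, and an exponential time-constant
#' fit to the mean surface warming.
#'
#' @param preset A `species_preset`.
#' @param I Irradiance after the shift, W/m^2 (600 in the experiments).
#' @param t_on Illumination onset, s; defaults to the preset's value
#'   (143 s for the hemisphere, 235 s for the branch).
#' @param alpha Tissue absorptivity.
#' @param duration Simulated time after onset, s.  `NULL` (the default)
#'   runs until the mean surface warming is within about 1% of its
#'   plateau, capped at 1800 s (hemispheres) / 1200 s (branches) after
#'   onset.
#' @param resolution Optional mesh triple.
#' @param config A [solver_config()] (`dt` defaults to 1 s).
#' @return List: `series`, `tau_s`, `dT_ss_K`, `fit`, `t_on`.
#' @export
run_dark_light <- function(preset, I = 600, t_on = NULL, alpha = 0.2,
                           duration = NULL, resolution = NULL,
                           config = solver_config()) {
  if (is.null(t_on)) t_on <- preset$t_on_s
  if (is.null(t_on) || is.na(t_on))
    stop("no illumination onset: give t_on for this species")
  case <- preset_case(preset, I = I, alpha = alpha, U_inlet = 0.002,
                      t_on = t_on, resolution = resolution)
  cfg <- config
  cap <- if (preset$coral$kind == "hemisphere") 1800 else 1200
  cfg$end_time <- if (is.null(duration)) NA else t_on + duration
  sol <- solve_transient(case, cfg,
                         max_time = t_on + cap)
  ft <- fit_time_constant(sol$series, t_on)
  list(series = sol$series, tau_s = ft$tau_s, dT_ss_K = ft$dT_ss_K,
       fit = ft, t_on = t_on, state = sol$state,
       flow_converged = sol$flow_converged)
}

#' Low-flow / high-flow comparison with per-species absorptivity calibration
#'
#' For each species, calibrates a single absorptivity inside the measured
#' range so the low-flow (0.002 m/s) steady warming at 600 W/m^2 matches
#' the species' reference low-flow value, freezes it, and predicts the
#' warming at high flow (0.013 m/s).  Because the energy equation is
#' linear in the absorbed power, the calibration is exact: warming scales
#' proportionally with absorptivity at fixed flow.
#'
#' @param presets List of `species_preset`s (default: the three
#'   steady-state species).
#' @param I Irradiance, W/m^2.
#' @param U_low,U_high The two flow speeds, m/s.
#' @param targets Optional named numeric vector of low-flow calibration
#'   targets in K; defaults to each preset's `table6_model_low_K`.
#' @param resolution Optional mesh triple applied to all species.
#' @param config A [solver_config()].
#' @return Data frame: species, calibrated alpha (with clipping flag),
#'   low- and high-flow mean warming, and the reference values.
#' @export
run_flow_comparison <- function(presets = NULL, I = 600,
                                U_low = 0.002, U_high = 0.013,
                                targets = NULL, resolution = NULL,
                                config = solver_config()) {
  if (is.null(presets)) {
    all <- make_presets()
    presets <- all[vapply(all, function(p) p$scenario == "steady", TRUE)]
  }
  rows <- lapply(presets, function(p) {
    target <- if (!is.null(targets)) targets[[p$name]]
    else p$table6_model_low_K
    if (is.null(target) || is.na(target))
      stop("no low-flow calibration target for ", p$name)
    rng <- p$alpha_range
    a_probe <- mean(rng)
    case_lo <- preset_case(p, I = I, alpha = a_probe, U_inlet = U_low,
                           resolution = resolution)
    sol_lo <- solve_steady(case_lo, config)
    dT_probe <- unname(sol_lo$warming["mean"])
    a_star <- a_probe * target / dT_probe
    clipped <- a_star < rng[1] || a_star > rng[2]
    a_star <- min(max(a_star, rng[1]), rng[2])
    dT_low <- dT_probe * a_star / a_probe   # exact by linearity
    case_hi <- preset_case(p, I = I, alpha = a_star, U_inlet = U_high,
                           resolution = resolution)
    sol_hi <- solve_steady(case_hi, config)
    data.frame(species = p$name, alpha = a_star, alpha_clipped = clipped,
               dT_low_K = dT_low,
               dT_high_K = unname(sol_hi$warming["mean"]),
               ref_low_K = target, ref_high_K = p$table6_model_high_K)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bulk-density sensitivity run for one species
#'
#' Dispatches the sensitivity study with the reference settings: inlet
#' 0.002 m/s at 26 C, heat flux 750 W/m^2, skeletal bulk volume varied
#' by -10%, 0, +10% at fixed mass.
#'
#' @param preset A `species_preset`.
#' @param alpha Tissue absorptivity.
#' @param resolution Optional mesh triple.
#' @param type `"steady"` or `"transient"` (see [sensitivity_study()]).
#' @param config A [solver_config()].
#' @return The [sensitivity_study()] table, with the run parameters
#'   attached as the `parameters` attribute.
#' @export
run_sensitivity <- function(preset, alpha = 0.2, resolution = NULL,
                            type = "steady", config = solver_config()) {
  if (is.null(resolution)) resolution <- preset$desk_resolution
  params <- list(inlet_reference_pressure_Pa = 0,
                 inlet_temperature_C = 26,
                 inlet_velocity_m_s = 0.002,
                 skeletal_bulk_volume = "+/- 10%",
                 heat_flux_W_m2 = 750)
  tab <- sensitivity_study(chamber_domain(), preset$coral,
                           phi0 = preset$porosity, alpha = alpha,
                           perturbations = c(-0.1, 0, 0.1),
                           I = 750, U_inlet = 0.002,
                           resolution = resolution, type = type,
                           config = config)
  attr(tab, "parameters") <- params
  tab
}
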