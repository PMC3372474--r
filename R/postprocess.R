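#' Surface warming of the coral
#'
#' Warming of the tissue surface above ambient, evaluated over every
#' tissue cell with an exposed (fluid-facing) face: the area-weighted
#' mean, and the maximum (the hottest spot on the coral surface).
#'
#' @param state A `field_state` with a temperature field.
#' @param case An [fvm_case()] built on a coral mesh.
#' @param T_ref Ambient temperature; defaults to the inlet value.
#' @return Named numeric vector `c(mean = , max = )`, in K.
#' @export
surface_warming <- function(state, case, T_ref = NULL) {
  stopifnot(inherits(case, "fvm_case"))
  if (!length(case$surf_idx))
    stop("mesh has no tissue surface cells (empty chamber?)")
  if (is.null(T_ref)) T_ref <- default_ambient(case)
  dT <- as.vector(state$T)[case$surf_idx] - T_ref
  w <- case$surf_area / sum(case$surf_area)
  c(mean = sum(w * dT), max = max(dT))
}

#' Fit the exponential time constant of a warming series
#'
#' Nonlinear least squares of `dT(t) = dT_ss * (1 - exp(-(t - t_on)/tau))`
#' to the samples with `t >= t_on`, with `t_on` fixed from the schedule
#' and `dT_ss`, `tau` free.  Starting values come from the observed
#' plateau and the 63.2% crossing.
#'
#' @param series Data frame with columns `t_s` and a warming column.
#' @param t_on Illumination onset, s.
#' @param column Which warming column to fit (default `"dT_mean_K"`).
#' @return List: `tau_s`, `dT_ss_K`, `rmse_K`, and the `fit` object.
#' @export
fit_time_constant <- function(series, t_on, column = "dT_mean_K") {
  stopifnot(is.data.frame(series), "t_s" %in% names(series),
            column %in% names(series))
  d <- series[series$t_s >= t_on, c("t_s", column)]
  names(d) <- c("t", "dT")
  if (nrow(d) < 10) stop("too few samples after t_on to fit")
  if (!all(is.finite(d$dT))) stop("non-finite warming values")
  rng <- diff(range(d$dT))
  if (rng <= 0 || max(d$dT) <= 0)
    stop("flat or non-warming series: no time constant to fit")
  dT_ss0 <- max(d$dT)
  i63 <- which(d$dT >= 0.632 * dT_ss0)[1]
  tau0 <- max(d$t[i63] - t_on, diff(range(d$t)) / 20)
  fit <- minpack.lm::nlsLM(
    dT ~ dT_ss * (1 - exp(-(t - t_on) / tau)),
    data = d, start = list(dT_ss = dT_ss0, tau = tau0),
    lower = c(0, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(tau_s = unname(cf["tau"]), dT_ss_K = unname(cf["dT_ss"]),
       rmse_K = sqrt(mean(stats::residuals(fit)^2)), fit = fit)
}

#' Linear irradiance-response fit
#'
#' Ordinary least squares of surface warming against irradiance, the
#' relationship heat-transfer theory predicts to be linear.
#'
#' @param points Data frame with columns `I` (W/m^2) and `dT` (K), or a
#'   two-column matrix.
#' @return List of class `linear_fit`: `slope` (K per W/m^2),
#'   `intercept` (K), `r_squared` (NA when the response has no variance),
#'   and the `lm` fit.
#' @export
irradiance_response <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("I", "dT") %in% names(points)))
    names(points)[1:2] <- c("I", "dT")
  if (nrow(points) < 3) stop("need at least 3 (I, dT) points")
  fit <- stats::lm(dT ~ I, data = points)
  r2 <- if (stats::var(points$dT) > 0) summary(fit)$r.squared else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, fit = fit),
            class = "linear_fit")
}

#' @exportS3Method
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> dT = %.3e * I + %.3e   (R^2 = %s)\n", x$slope,
    x$intercept, if (is.na(x$r_squared)) "undefined"
    else sprintf("%.4f", x$r_squared)))
  invisible(x)
}

#' Extract cross-sectional slices of axial velocity and temperature
#'
#' Nearest-cell extraction (no interpolation): slice values equal the
#' field values of the cells the plane passes through.  The coral
#' cross-section mask is returned alongside so plots can outline it.
#'
#' @param state A `field_state`.
#' @param case An [fvm_case()].
#' @param axis `"x"`, `"y"` or `"z"`: the axis the planes are normal to.
#' @param at Numeric vector of plane coordinates, m.
#' @return List of slices; each holds `at` (requested), `coord` (actual
#'   cell-centre coordinate), the two in-plane coordinate vectors, and
#'   matrices `u_axial`, `T`, `coral` (logical mask).
#' @export
extract_slices <- function(state, case, axis = c("y", "x", "z"), at = 0) {
  axis <- match.arg(axis)
  mesh <- case$mesh
  cc <- switch(axis, x = mesh$x, y = mesh$y, z = mesh$z)
  lim <- switch(axis, x = c(0, mesh$domain$length),
                y = c(0, mesh$domain$width), z = c(0, mesh$domain$height))
  lapply(at, function(a) {
    if (a < lim[1] || a > lim[2])
      stop(sprintf("plane %s = %g lies outside the domain", axis, a))
    i <- which.min(abs(cc - a))
    sl <- switch(axis,
      x = list(c1 = mesh$y, c2 = mesh$z, u = state$u[i, , ],
               T = state$T[i, , ], coral = case$mesh$zone[i, , ] != 0L),
      y = list(c1 = mesh$x, c2 = mesh$z, u = state$u[, i, ],
               T = state$T[, i, ], coral = case$mesh$zone[, i, ] != 0L),
      z = list(c1 = mesh$x, c2 = mesh$y, u = state$u[, , i],
               T = state$T[, , i], coral = case$mesh$zone[, , i] != 0L))
    list(axis = axis, at = a, coord = cc[i], c1 = sl$c1, c2 = sl$c2,
         u_axial = sl$u, T = sl$T, coral = sl$coral)
  })
}

#' Grid-independence study
#'
#' Re-solves one steady case on successively finer grids and tabulates
#' the surface warming against cell count; the solution is judged
#' grid-independent when the change between the two finest grids drops
#' below `threshold` (2% by default).
#'
#' @param domain,coral Chamber and coral description.
#' @param materials,porous,bcs,source As for [fvm_case()].
#' @param resolutions List of at least 3 `c(nx, ny, nz)` triples, coarse
#'   to fine.
#' @param config A [solver_config()].
#' @param threshold Relative-change threshold for the asymptotic flag.
#' @return Data frame: cells, mean/max warming, relative change from the
#'   previous grid, and the asymptotic flag on the finest pair.
#' @export
grid_independence_study <- function(domain, coral, materials, porous,
                                    bcs, source, resolutions,
                                    config = solver_config(),
                                    threshold = 0.02) {
  if (length(resolutions) < 3)
    stop("a grid-independence study needs at least 3 resolutions")
  rows <- lapply(resolutions, function(res) {
    mesh <- build_mesh(domain, coral, res)
    case <- fvm_case(mesh, materials, porous, bcs, source)
    sol <- solve_steady(case, config)
    data.frame(nx = res[1], ny = res[2], nz = res[3],
               cells = prod(res),
               dT_mean_K = unname(sol$warming["mean"]),
               dT_max_K = unname(sol$warming["max"]))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$cells), ]
  tab$rel_change <- c(NA, abs(diff(tab$dT_mean_K)) /
                        abs(tab$dT_mean_K[-nrow(tab)]))
  tab$asymptotic <- FALSE
  tab$asymptotic[nrow(tab)] <- tab$rel_change[nrow(tab)] < threshold
  tab
}

#' Skeletal bulk-density sensitivity study
#'
#' Perturbs the skeletal bulk volume by the given fractions at fixed
#' skeletal mass, which rescales the bulk density (rho_b / (1 + e)) and
#' hence the skeletal porosity and all porosity-derived properties, then
#' re-solves the heated steady state (or a transient trajectory) at each
#' perturbation.  The geometry is held fixed; only the material closure
#' changes, mirroring an uncertainty in the density estimate.
#'
#' @param domain,coral Chamber and coral description.
#' @param phi0 Baseline skeletal porosity.
#' @param alpha Tissue absorptivity used for the heating.
#' @param perturbations Bulk-volume fractions, e.g. `c(-0.1, 0, 0.1)`.
#' @param I Irradiance, W/m^2 (750 for the reference study).
#' @param U_inlet Inlet flow, m/s.
#' @param resolution Mesh resolution triple.
#' @param materials A [material_set()].
#' @param tissue_phi Tissue-shell porosity (default 0.05).
#' @param type `"steady"` (default: converged warming per perturbation)
#'   or `"transient"` (warming trajectories; much slower).
#' @param config,duration Solver settings; `duration` caps transient runs.
#' @return Data frame with one row per perturbation: perturbed porosity
#'   and bulk density, mean and max surface warming; for transient runs
#'   the trajectories are attached as the `series` attribute.
#' @export
sensitivity_study <- function(domain, coral, phi0, alpha,
                              perturbations = c(-0.1, 0, 0.1),
                              I = 750, U_inlet = 0.002,
                              resolution, materials = material_set(),
                              tissue_phi = 0.05,
                              type = c("steady", "transient"),
                              config = solver_config(), duration = 900) {
  type <- match.arg(type)
  stopifnot(all(perturbations >= -0.2 & perturbations <= 0.2))
  rho_t <- 2.94
  mesh <- build_mesh(domain, coral, resolution)
  bcs <- boundary_set(U_inlet = U_inlet)
  src <- irradiance_source(I, alpha,
                           t_on = if (type == "transient") 10 else 0)
  d <- 2 * coral$radius
  series <- list()
  rows <- lapply(perturbations, function(e) {
    rho_b <- bulk_density_from_porosity(phi0, rho_t) / (1 + e)
    phi <- porosity_from_density(rho_b, rho_t)
    porous <- list(tissue = porous_zone_spec(tissue_phi, d),
                   skeleton = porous_zone_spec(phi, d))
    case <- fvm_case(mesh, materials, porous, bcs, src)
    if (type == "steady") {
      sol <- solve_steady(case, config)
      w <- sol$warming
    } else {
      cfg <- config; cfg$end_time <- duration
      sol <- solve_transient(case, cfg)
      n <- nrow(sol$series)
      w <- c(mean = sol$series$dT_mean_K[n], max = sol$series$dT_max_K[n])
      series[[as.character(e)]] <<- sol$series
    }
    data.frame(volume_perturbation = e, bulk_density_g_cm3 = rho_b,
               skeletal_porosity = phi,
               dT_mean_K = unname(w["mean"]), dT_max_K = unname(w["max"]))
  })
  out <- do.call(rbind, rows)
  if (type == "transient") attr(out, "series") <- series
  out
}
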