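#' Boundary-condition set for the flow chamber
#'
#' Encodes the validation chamber's boundary conditions: fixed-value inlet
#' velocity and temperature, fixed-value upward percolation through the
#' sandy bottom, fixed reference pressure and zero-normal-gradient velocity
#' at the outlet, zero-gradient temperature at the outlet, and slip
#' (impermeable, shear-free) walls on the top and sides.
#'
#' The bottom patch is switchable: `"inflow"` (fixed upward 0.001 m/s
#' through the open sand floor with fixed 26 C temperature, the default;
#' the floor under the coral footprint is impermeable, since percolation
#' forced through the colony base would flush the skeleton at the bed
#' speed and clamp surface warming far below anything observed),
#' `"inflow_full"` (upward inflow everywhere, including under the
#' coral), `"slip"` or `"no_slip"` (both impermeable; temperature fixed
#' when `fix_wall_T`).  `"no_slip"` top/bottom walls turn the chamber
#' into a plane channel, used for analytic flow verification.
#'
#' @param U_inlet Inlet speed along the chamber, m/s.
#' @param U_bottom Upward percolation speed at the bottom, m/s (only used
#'   when `bottom_mode = "inflow"`).
#' @param T_value Fixed temperature at inlet/bottom, degrees C.
#' @param p_outlet Outlet reference pressure (kinematic), default 0.
#' @param bottom_mode,top_mode,sides_mode Patch behaviour, see Details.
#' @param fix_wall_T Fix the temperature of solid (`no_slip`/`slip`)
#'   bottom walls at `T_value`?  Default `TRUE` for the bottom (the sand
#'   bed is thermostatted), walls and top are always adiabatic.
#' @return An object of class `boundary_set`: a list of per-patch
#'   conditions for velocity, pressure and temperature.
#' @export
boundary_set <- function(U_inlet = 0.002, U_bottom = 0.001, T_value = 26,
                         p_outlet = 0,
                         bottom_mode = c("inflow", "inflow_full", "slip",
                                         "no_slip"),
                         top_mode = c("slip", "no_slip"),
                         sides_mode = c("slip", "no_slip"),
                         fix_wall_T = TRUE) {
  bottom_mode <- match.arg(bottom_mode)
  top_mode <- match.arg(top_mode)
  sides_mode <- match.arg(sides_mode)
  fv <- function(v) list(type = "fixed_value", value = v)
  zg <- function() list(type = "zero_gradient")
  sl <- function() list(type = "slip")
  ns <- function() list(type = "no_slip")
  bottom_U <- switch(bottom_mode,
                     inflow = fv(c(0, 0, U_bottom)),
                     inflow_full = fv(c(0, 0, U_bottom)),
                     slip = sl(), no_slip = ns())
  bottom_T <- if (startsWith(bottom_mode, "inflow") || fix_wall_T)
    fv(T_value) else zg()
  structure(list(
    inlet  = list(U = fv(c(U_inlet, 0, 0)), p = zg(), T = fv(T_value)),
    outlet = list(U = zg(), p = fv(p_outlet), T = zg()),
    bottom = list(U = bottom_U, p = zg(), T = bottom_T),
    top    = list(U = switch(top_mode, slip = sl(), no_slip = ns()),
                  p = zg(), T = zg()),
    sides  = list(U = switch(sides_mode, slip = sl(), no_slip = ns()),
                  p = zg(), T = zg())
  ), class = "boundary_set", bottom_mode = bottom_mode)
}

#' Solver configuration
#'
#' @param dt Time step for transient runs, s (default 1.0).
#' @param end_time End of a transient run, s (`NA` means run until the
#'   warming plateaus).
#' @param urf_u,urf_p Under-relaxation factors for momentum and pressure.
#' @param tol Convergence tolerance on normalised residuals.
#' @param max_outer Maximum SIMPLE outer iterations.
#' @param n_sweeps Damped-Jacobi sweeps per momentum solve.
#' @param energy_scheme Convection scheme for the energy equation:
#'   `"limited"` (van Leer limited linear via deferred correction, the
#'   default) or `"upwind"` (pure first order).
#' @param momentum_scheme Convection scheme for the momentum equations
#'   (same options; default `"upwind"`).
#' @param use_forchheimer Include the inertial porous loss term?
#' @param verbose Print residuals every `verbose` iterations (0 = silent).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 1.0, end_time = NA, urf_u = 0.7, urf_p = 0.3,
                          tol = 1e-6, max_outer = 600, n_sweeps = 8,
                          energy_scheme = c("limited", "upwind"),
                          momentum_scheme = c("upwind", "limited"),
                          use_forchheimer = FALSE, verbose = 0) {
  energy_scheme <- match.arg(energy_scheme)
  momentum_scheme <- match.arg(momentum_scheme)
  stopifnot(dt > 0, urf_u > 0, urf_u <= 1, urf_p > 0, urf_p <= 1,
            tol > 0, max_outer >= 1, n_sweeps >= 1)
  structure(list(dt = dt, end_time = end_time, urf_u = urf_u, urf_p = urf_p,
                 tol = tol, max_outer = max_outer, n_sweeps = n_sweeps,
                 energy_scheme = energy_scheme,
                 momentum_scheme = momentum_scheme,
                 use_forchheimer = use_forchheimer, verbose = verbose),
            class = "solver_config")
}

#' Irradiance source description
#'
#' Shortwave illumination of intensity `I` switched on at `t_on`, heating
#' the exposed tissue shell (surface absorption; in-depth attenuation is
#' not modelled).  Two deposition geometries are available:
#'
#' * `"projected"` (default): a collimated overhead beam;
#'   `alpha * I * sin(theta)` per unit horizontal area enters the topmost
#'   tissue cell of each irradiated grid column, so the absorbed power is
#'   `alpha * I * A_projected`.
#' * `"surface"`: the flux `alpha * I * sin(theta)` is applied per unit
#'   exposed tissue area over the whole lit surface, the way a surface
#'   heat-flux boundary treats an illuminated patch.  The absorbed power
#'   is `alpha * I * A_lit` with `A_lit` the analytic lit area (curved
#'   cap of a hemisphere; lateral surface plus top of a branch),
#'   distributed over the stair-step surface cells in proportion to
#'   their exposed area and normalised so the total matches the analytic
#'   lit area.
#'
#' @param I Irradiance, W/m^2.
#' @param alpha Tissue absorptivity in `[0, 1]`.
#' @param theta Beam elevation angle in degrees (90 = overhead).
#' @param t_on Illumination onset, s (0 for steady runs).
#' @param deposition `"surface"` or `"projected"`, see Details.
#' @return An object of class `irradiance_source`.
#' @export
irradiance_source <- function(I, alpha, theta = 90, t_on = 0,
                              deposition = c("projected", "surface")) {
  deposition <- match.arg(deposition)
  stopifnot(I >= 0, alpha >= 0, alpha <= 1, t_on >= 0)
  structure(list(I = I, alpha = alpha, theta = theta, t_on = t_on,
                 deposition = deposition),
            class = "irradiance_source")
}

# ---------------------------------------------------------------------------
# Case precomputation: geometry factors, zone property fields, BC digests.
# All solver internals work on this object.

zeros3 <- function(case) array(0, dim = c(case$nx, case$ny, case$nz))

#' Assemble a finite-volume case
#'
#' Precomputes everything the flow and energy discretisations need: face
#' areas and distances on the graded grid, per-cell porous resistances and
#' effective thermal properties by zone, the irradiance deposition cells,
#' and the per-patch boundary digests.
#'
#' @param mesh A [build_mesh()] result.
#' @param materials A [material_set()].
#' @param porous List with elements `tissue` and `skeleton`, each a
#'   [porous_zone_spec()] (ignored for an empty chamber).
#' @param bcs A [boundary_set()].
#' @param source An [irradiance_source()].
#' @return An object of class `fvm_case`.
#' @export
fvm_case <- function(mesh, materials = material_set(),
                     porous = NULL, bcs = boundary_set(),
                     source = irradiance_source(0, 0)) {
  stopifnot(inherits(mesh, "coral_mesh"), inherits(materials, "material_set"),
            inherits(bcs, "boundary_set"),
            inherits(source, "irradiance_source"))
  nx <- mesh$nx; ny <- mesh$ny; nz <- mesh$nz
  x <- mesh$x; y <- mesh$y; z <- mesh$z
  has_coral <- any(mesh$zone != 0L)
  if (has_coral && (is.null(porous$tissue) || is.null(porous$skeleton)))
    stop("a coral mesh needs porous$tissue and porous$skeleton specs")

  ones_yz <- matrix(1, ny, nz); ones_xz <- matrix(1, nx, nz)
  ones_xy <- matrix(1, nx, ny)
  Ax_b <- mesh$dy %o% mesh$dz          # boundary/x-face areas, (ny, nz)
  Ay_b <- mesh$dx %o% mesh$dz
  Az_b <- mesh$dx %o% mesh$dy

  geom <- list(
    Ax_b = Ax_b, Ay_b = Ay_b, Az_b = Az_b,
    # internal faces, per direction
    Ax = outer(rep(1, nx - 1), Ax_b),
    Ay = aperm(outer(rep(1, ny - 1), Ay_b), c(2, 1, 3)),
    Az = aperm(outer(rep(1, nz - 1), Az_b), c(2, 3, 1)),
    invd_x = outer(1 / diff(x), ones_yz),
    invd_y = aperm(outer(1 / diff(y), ones_xz), c(2, 1, 3)),
    invd_z = aperm(outer(1 / diff(z), ones_xy), c(2, 3, 1)),
    wx = outer((mesh$xf[2:nx] - x[1:(nx - 1)]) / diff(x), ones_yz),
    wy = aperm(outer((mesh$yf[2:ny] - y[1:(ny - 1)]) / diff(y), ones_xz),
               c(2, 1, 3)),
    wz = aperm(outer((mesh$zf[2:nz] - z[1:(nz - 1)]) / diff(z), ones_xy),
               c(2, 3, 1)),
    # half-distances to each boundary
    hdx_lo = mesh$dx[1] / 2, hdx_hi = mesh$dx[nx] / 2,
    hdy_lo = mesh$dy[1] / 2, hdy_hi = mesh$dy[ny] / 2,
    hdz_lo = mesh$dz[1] / 2, hdz_hi = mesh$dz[nz] / 2
  )

  # per-cell zone properties
  nuD <- array(0, c(nx, ny, nz))
  Fcoef <- array(0, c(nx, ny, nz))
  k_eff <- array(materials$k_f, c(nx, ny, nz))
  rho_cp <- array(materials$rho_f * materials$cp_f, c(nx, ny, nz))
  if (has_coral) {
    for (zz in c(tissue = 1L, skeleton = 2L)) {
      spec <- if (zz == 1L) porous$tissue else porous$skeleton
      sel <- mesh$zone == zz
      nuD[sel] <- materials$nu * spec$D
      Fcoef[sel] <- spec$F
      ep <- effective_props(spec$phi, materials)
      k_eff[sel] <- ep$k_eff
      rho_cp[sel] <- ep$rho_cp_eff
    }
  }

  # tissue surface cells (tissue with an exposed fluid face) + exposed area
  surf <- surface_cells(mesh)

  # irradiance deposition cells and the per-cell lit area they represent
  src_idx <- integer(0); src_area <- numeric(0)
  dep <- if (is.null(source$deposition)) "projected" else source$deposition
  if (has_coral && dep == "projected") {
    # collimated overhead beam: topmost coral cell of each column
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      ks <- which(mesh$zone[i, j, ] != 0L)
      if (length(ks)) {
        k <- max(ks)
        src_idx <- c(src_idx, i + nx * (j - 1L) + nx * ny * (k - 1L))
        src_area <- c(src_area, mesh$dx[i] * mesh$dy[j])
      }
    }
  } else if (has_coral) {
    # uniform surface flux over the lit tissue: stair-step exposed areas
    # rescaled so they sum to the analytic lit area
    coral <- mesh$coral
    A_lit <- if (coral$kind == "hemisphere") {
      2 * pi * coral$radius^2
    } else {
      2 * pi * coral$radius * coral$height + pi * coral$radius^2
    }
    src_idx <- surf$idx
    src_area <- surf$area * A_lit / sum(surf$area)
  }

  # open-sand mask of the bottom patch: bed percolation enters only
  # outside the coral footprint unless bottom_mode = "inflow_full"
  bmode <- attr(bcs, "bottom_mode")
  if (is.null(bmode)) bmode <- "inflow"
  bottom_open <- matrix(1, nx, ny)
  if (bmode == "inflow" && has_coral)
    bottom_open[mesh$zone[, , 1] != 0L] <- 0

  structure(
    list(mesh = mesh, materials = materials, porous = porous,
         bcs = bcs, source = source,
         nx = nx, ny = ny, nz = nz, vol = mesh$vol, geom = geom,
         pat = pressure_pattern(nx, ny, nz),
         dilu_str = dilu_structure(nx, ny, nz),
         nuD = nuD, Fcoef = Fcoef, k_eff = k_eff, rho_cp = rho_cp,
         src_idx = src_idx, src_area = src_area,
         surf_idx = surf$idx, surf_area = surf$area,
         bottom_open = bottom_open,
         has_coral = has_coral),
    class = "fvm_case"
  )
}

# Coral surface cells and their exposed (fluid-facing) areas.
surface_cells <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny; nz <- mesh$nz
  zone <- mesh$zone
  if (!any(zone != 0L)) return(list(idx = integer(0), area = numeric(0)))
  area <- array(0, c(nx, ny, nz))
  coral <- zone != 0L
  Ax <- mesh$dy %o% mesh$dz; Ay <- mesh$dx %o% mesh$dz
  Az <- mesh$dx %o% mesh$dy
  # x-direction exposures
  expo <- coral[2:nx, , ] & !coral[1:(nx - 1), , ]
  area[2:nx, , ][expo] <- area[2:nx, , ][expo] +
    outer(rep(1, nx - 1), Ax)[expo]
  expo <- coral[1:(nx - 1), , ] & !coral[2:nx, , ]
  area[1:(nx - 1), , ][expo] <- area[1:(nx - 1), , ][expo] +
    outer(rep(1, nx - 1), Ax)[expo]
  # y-direction
  Ay3 <- aperm(outer(rep(1, ny - 1), Ay), c(2, 1, 3))
  expo <- coral[, 2:ny, ] & !coral[, 1:(ny - 1), ]
  area[, 2:ny, ][expo] <- area[, 2:ny, ][expo] + Ay3[expo]
  expo <- coral[, 1:(ny - 1), ] & !coral[, 2:ny, ]
  area[, 1:(ny - 1), ][expo] <- area[, 1:(ny - 1), ][expo] + Ay3[expo]
  # z-direction (top exposure; also count the chamber-top side if coral
  # reaches it, which it does not in practice)
  Az3 <- aperm(outer(rep(1, nz - 1), Az), c(2, 3, 1))
  expo <- coral[, , 2:nz] & !coral[, , 1:(nz - 1)]
  area[, , 2:nz][expo] <- area[, , 2:nz][expo] + Az3[expo]
  expo <- coral[, , 1:(nz - 1)] & !coral[, , 2:nz]
  area[, , 1:(nz - 1)][expo] <- area[, , 1:(nz - 1)][expo] + Az3[expo]
  sel <- which(zone == 1L & area > 0)
  list(idx = sel, area = area[sel])
}

# Initial field state: uniform inlet velocity, reference pressure,
# ambient temperature, fluxes from the velocity field.
init_state <- function(case, T0 = 26) {
  bcs <- case$bcs
  Uin <- if (bcs$inlet$U$type == "fixed_value") bcs$inlet$U$value[1] else 0
  st <- structure(
    list(u = array(Uin, c(case$nx, case$ny, case$nz)),
         v = zeros3(case), w = zeros3(case),
         p = zeros3(case), T = array(T0, c(case$nx, case$ny, case$nz)),
         t = 0),
    class = "field_state")
  st <- compute_fluxes_linear(case, st)
  st
}

# Face fluxes by plain linear interpolation (used for initialisation;
# the SIMPLE loop replaces these with Rhie-Chow corrected fluxes).
compute_fluxes_linear <- function(case, st) {
  g <- case$geom; nx <- case$nx; ny <- case$ny; nz <- case$nz
  phi_x <- array(0, c(nx + 1, ny, nz))
  phi_y <- array(0, c(nx, ny + 1, nz))
  phi_z <- array(0, c(nx, ny, nz + 1))
  phi_x[2:nx, , ] <- g$Ax *
    ((1 - g$wx) * st$u[1:(nx - 1), , ] + g$wx * st$u[2:nx, , ])
  phi_y[, 2:ny, ] <- g$Ay *
    ((1 - g$wy) * st$v[, 1:(ny - 1), ] + g$wy * st$v[, 2:ny, ])
  phi_z[, , 2:nz] <- g$Az *
    ((1 - g$wz) * st$w[, , 1:(nz - 1)] + g$wz * st$w[, , 2:nz])
  st$phi_x <- phi_x; st$phi_y <- phi_y; st$phi_z <- phi_z
  apply_boundary_fluxes(case, st)
}

# Boundary-face fluxes implied by the boundary conditions.
apply_boundary_fluxes <- function(case, st) {
  g <- case$geom; bcs <- case$bcs
  nx <- case$nx; ny <- case$ny; nz <- case$nz
  # inlet (x low)
  st$phi_x[1, , ] <- if (bcs$inlet$U$type == "fixed_value")
    bcs$inlet$U$value[1] * g$Ax_b else 0
  # outlet (x high): zero-normal-gradient extrapolation
  st$phi_x[nx + 1, , ] <- if (bcs$outlet$U$type == "zero_gradient")
    st$u[nx, , ] * g$Ax_b else 0
  # sides (y low/high): slip or no_slip are impermeable
  st$phi_y[, 1, ] <- 0
  st$phi_y[, ny + 1, ] <- 0
  # bottom (z low): percolation only through the open sand floor
  st$phi_z[, , 1] <- if (bcs$bottom$U$type == "fixed_value")
    bcs$bottom$U$value[3] * g$Az_b * case$bottom_open else 0
  # top (z high): impermeable
  st$phi_z[, , nz + 1] <- 0
  st
}

#' Apply boundary conditions to a field state
#'
#' Resets every boundary-face flux (and hence the boundary values the
#' discretisation sees) according to the boundary set attached to the
#' case.  Interior cell values are untouched; in this collocated scheme
#' boundary conditions otherwise live inside the matrix assembly.
#'
#' @param state A `field_state`.
#' @param case An [fvm_case()] (its `bcs` are applied).
#' @return The state with consistent boundary fluxes.
#' @export
apply_boundary_conditions <- function(state, case) {
  stopifnot(inherits(state, "field_state"), inherits(case, "fvm_case"))
  for (p in c("inlet", "outlet", "bottom", "top", "sides")) {
    if (is.null(case$bcs[[p]])) stop("missing boundary patch: ", p)
    for (f in c("U", "p", "T"))
      if (is.null(case$bcs[[p]][[f]]))
        stop("missing ", f, " condition on patch ", p)
  }
  apply_boundary_fluxes(case, state)
}

#' Mean inlet-face speed implied by a state
#' @param case An [fvm_case()].
#' @param state A `field_state`.
#' @return Area-weighted mean speed through the inlet, m/s.
#' @export
inlet_mean_speed <- function(case, state) {
  sum(state$phi_x[1, , ]) / sum(case$geom$Ax_b)
}
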