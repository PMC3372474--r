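# Conjugate energy transport in the chamber: advection by the superficial
# velocity field, diffusion with zone-wise effective conductivity (local
# thermal equilibrium in the porous coral), and an irradiance source
# deposited in the topmost tissue cell of every irradiated column.
#
# The discrete system is assembled in Watts: convective face coefficients
# rho_f*Cp_f*phi (W/K), diffusive k_face*A/d (W/K), storage
# rhoCp_eff*V/dt (W/K), source alpha*I*sin(theta)*dx*dy (W).

energy_system <- function(case, st) {
  g <- case$geom; mat <- case$materials
  nx <- case$nx; ny <- case$ny; nz <- case$nz
  pat <- case$pat
  rcp <- mat$rho_f * mat$cp_f
  k <- case$k_eff
  diagv <- numeric(pat$ncell)
  rhs <- numeric(pat$ncell)

  # internal faces: distance-weighted harmonic conductivity
  kP <- k[1:(nx - 1), , , drop = FALSE]; kE <- k[2:nx, , , drop = FALSE]
  kfx <- 1 / ((1 - g$wx) / kP + g$wx / kE)
  Dx <- kfx * g$Ax * g$invd_x
  ce <- rcp * st$phi_x[2:nx, , , drop = FALSE]
  off_xPE <- -(as.vector(Dx) + pmax(-as.vector(ce), 0))
  off_xEP <- -(as.vector(Dx) + pmax(as.vector(ce), 0))
  diagv[pat$ixP] <- diagv[pat$ixP] + as.vector(Dx) + pmax(as.vector(ce), 0)
  diagv[pat$ixE] <- diagv[pat$ixE] + as.vector(Dx) + pmax(-as.vector(ce), 0)

  kP <- k[, 1:(ny - 1), , drop = FALSE]; kN <- k[, 2:ny, , drop = FALSE]
  kfy <- 1 / ((1 - g$wy) / kP + g$wy / kN)
  Dy <- kfy * g$Ay * g$invd_y
  cn <- rcp * st$phi_y[, 2:ny, , drop = FALSE]
  off_yPN <- -(as.vector(Dy) + pmax(-as.vector(cn), 0))
  off_yNP <- -(as.vector(Dy) + pmax(as.vector(cn), 0))
  diagv[pat$iyP] <- diagv[pat$iyP] + as.vector(Dy) + pmax(as.vector(cn), 0)
  diagv[pat$iyN] <- diagv[pat$iyN] + as.vector(Dy) + pmax(-as.vector(cn), 0)

  kP <- k[, , 1:(nz - 1), drop = FALSE]; kT <- k[, , 2:nz, drop = FALSE]
  kfz <- 1 / ((1 - g$wz) / kP + g$wz / kT)
  Dz <- kfz * g$Az * g$invd_z
  ct <- rcp * st$phi_z[, , 2:nz, drop = FALSE]
  off_zPT <- -(as.vector(Dz) + pmax(-as.vector(ct), 0))
  off_zTP <- -(as.vector(Dz) + pmax(as.vector(ct), 0))
  diagv[pat$izP] <- diagv[pat$izP] + as.vector(Dz) + pmax(as.vector(ct), 0)
  diagv[pat$izT] <- diagv[pat$izT] + as.vector(Dz) + pmax(-as.vector(ct), 0)

  # boundary patches
  bterm <- function(bcT, ids, kslab, A, hd, flux_in) {
    # flux_in: volumetric inflow through the boundary face
    cin <- rcp * pmax(flux_in, 0)
    cout <- rcp * pmax(-flux_in, 0)
    if (bcT$type == "fixed_value") {
      Db <- kslab * A / hd
      diagv[ids] <<- diagv[ids] + as.vector(Db) + as.vector(cout)
      rhs[ids] <<- rhs[ids] + (as.vector(Db) + as.vector(cin)) * bcT$value
    } else {
      # zero-gradient / slip: adiabatic, outflow leaves at the cell value
      diagv[ids] <<- diagv[ids] + as.vector(cout)
    }
  }
  bcs <- case$bcs
  bterm(bcs$inlet$T, as.vector(pat$id[1, , ]), k[1, , ], g$Ax_b, g$hdx_lo,
        st$phi_x[1, , ])
  bterm(bcs$outlet$T, as.vector(pat$id[nx, , ]), k[nx, , ], g$Ax_b,
        g$hdx_hi, -st$phi_x[nx + 1, , ])
  bterm(bcs$sides$T, as.vector(pat$id[, 1, ]), k[, 1, ], g$Ay_b, g$hdy_lo,
        st$phi_y[, 1, ])
  bterm(bcs$sides$T, as.vector(pat$id[, ny, ]), k[, ny, ], g$Ay_b,
        g$hdy_hi, -st$phi_y[, ny + 1, ])
  bterm(bcs$bottom$T, as.vector(pat$id[, , 1]), k[, , 1], g$Az_b, g$hdz_lo,
        st$phi_z[, , 1])
  bterm(bcs$top$T, as.vector(pat$id[, , nz]), k[, , nz], g$Az_b, g$hdz_hi,
        -st$phi_z[, , nz + 1])

  M <- sparseMatrix(i = pat$i, j = pat$j,
                    x = c(off_xPE, off_xEP, off_yPN, off_yNP,
                          off_zPT, off_zTP, diagv),
                    dims = c(pat$ncell, pat$ncell))
  # per-cell stencil vectors for the DILU preconditioner
  n <- pat$ncell
  uE <- numeric(n); uN <- numeric(n); uT <- numeric(n)
  lW <- numeric(n); lS <- numeric(n); lB <- numeric(n)
  uE[pat$ixP] <- off_xPE; lW[pat$ixE] <- off_xEP
  uN[pat$iyP] <- off_yPN; lS[pat$iyN] <- off_yNP
  uT[pat$izP] <- off_zPT; lB[pat$izT] <- off_zTP
  stencil <- list(diag = diagv, uE = uE, uN = uN, uT = uT,
                  lW = lW, lS = lS, lB = lB)
  list(M = M, rhs_bc = rhs, pat = pat, stencil = stencil)
}

# DILU preconditioner application for an energy system (optionally with
# an added storage diagonal for transient steps).
energy_psolve <- function(case, sys, storage = NULL) {
  stn <- sys$stencil
  if (!is.null(storage)) stn$diag <- stn$diag + storage
  d <- dilu_factor(stn, case$dilu_str)
  dilu_psolve(stn, d, case$dilu_str)
}

# Higher-order (van Leer limited) deferred-correction source for the
# energy convection terms.  The implicit operator stays first-order
# upwind; this adds the conservative antidiffusive face corrections
# c_f * (T_face_limited - T_face_upwind) to the right-hand side, scattered
# with opposite signs to the two cells sharing each face.  Faces adjacent
# to a boundary (no second-upstream cell) stay upwind.
ho_correction <- function(case, st, Tarr, carrier = NULL) {
  g <- case$geom; pat <- case$pat
  nx <- case$nx; ny <- case$ny; nz <- case$nz
  rcp <- if (is.null(carrier))
    case$materials$rho_f * case$materials$cp_f else carrier
  rhs <- numeric(pat$ncell)
  tiny <- 1e-24

  limit_dir <- function(cc, TP, TE, Tc, TW, TEE, hasW, hasEE) {
    dPE <- TE - TP
    pos <- cc > 0
    # gradient ratio of the donor cell
    num <- ifelse(pos, TP - TW, TE - TEE)
    den <- ifelse(pos, dPE, -dPE)
    r <- num * den / (den * den + tiny)
    psi <- (r + abs(r)) / (1 + abs(r))          # van Leer
    psi[ifelse(pos, !hasW, !hasEE)] <- 0
    Tu <- ifelse(pos, TP, TE)
    Tf <- Tu + psi * (Tc - Tu)
    cc * (Tf - Tu)
  }

  # x-direction
  cc <- rcp * st$phi_x[2:nx, , , drop = FALSE]
  TP <- Tarr[1:(nx - 1), , , drop = FALSE]
  TE <- Tarr[2:nx, , , drop = FALSE]
  Tc <- (1 - g$wx) * TP + g$wx * TE
  TW <- Tarr[c(1, 1:(nx - 2)), , , drop = FALSE]
  TEE <- Tarr[c(3:nx, nx), , , drop = FALSE]
  hasW <- array(rep(c(FALSE, rep(TRUE, nx - 2)), ny * nz), c(nx - 1, ny, nz))
  hasEE <- array(rep(c(rep(TRUE, nx - 2), FALSE), ny * nz), c(nx - 1, ny, nz))
  ex <- limit_dir(cc, TP, TE, Tc, TW, TEE, hasW, hasEE)
  rhs[pat$ixP] <- rhs[pat$ixP] - as.vector(ex)
  rhs[pat$ixE] <- rhs[pat$ixE] + as.vector(ex)

  # y-direction
  cc <- rcp * st$phi_y[, 2:ny, , drop = FALSE]
  TP <- Tarr[, 1:(ny - 1), , drop = FALSE]
  TE <- Tarr[, 2:ny, , drop = FALSE]
  Tc <- (1 - g$wy) * TP + g$wy * TE
  TW <- Tarr[, c(1, 1:(ny - 2)), , drop = FALSE]
  TEE <- Tarr[, c(3:ny, ny), , drop = FALSE]
  hasW <- aperm(array(rep(c(FALSE, rep(TRUE, ny - 2)), nx * nz),
                      c(ny - 1, nx, nz)), c(2, 1, 3))
  hasEE <- aperm(array(rep(c(rep(TRUE, ny - 2), FALSE), nx * nz),
                       c(ny - 1, nx, nz)), c(2, 1, 3))
  ey <- limit_dir(cc, TP, TE, Tc, TW, TEE, hasW, hasEE)
  rhs[pat$iyP] <- rhs[pat$iyP] - as.vector(ey)
  rhs[pat$iyN] <- rhs[pat$iyN] + as.vector(ey)

  # z-direction
  cc <- rcp * st$phi_z[, , 2:nz, drop = FALSE]
  TP <- Tarr[, , 1:(nz - 1), drop = FALSE]
  TE <- Tarr[, , 2:nz, drop = FALSE]
  Tc <- (1 - g$wz) * TP + g$wz * TE
  TW <- Tarr[, , c(1, 1:(nz - 2)), drop = FALSE]
  TEE <- Tarr[, , c(3:nz, nz), drop = FALSE]
  hasW <- aperm(array(rep(c(FALSE, rep(TRUE, nz - 2)), nx * ny),
                      c(nz - 1, nx, ny)), c(2, 3, 1))
  hasEE <- aperm(array(rep(c(rep(TRUE, nz - 2), FALSE), nx * ny),
                       c(nz - 1, nx, ny)), c(2, 3, 1))
  ez <- limit_dir(cc, TP, TE, Tc, TW, TEE, hasW, hasEE)
  rhs[pat$izP] <- rhs[pat$izP] - as.vector(ez)
  rhs[pat$izT] <- rhs[pat$izT] + as.vector(ez)
  rhs
}

# Irradiance source vector in W (0 when the lamp is off).
source_vector <- function(case, on = TRUE) {
  src <- numeric(case$nx * case$ny * case$nz)
  if (on && length(case$src_idx) && case$source$I > 0) {
    s <- case$source
    src[case$src_idx] <- s$alpha * s$I * sin(s$theta * pi / 180) *
      case$src_area
  }
  src
}

#' Solve the steady energy equation on a converged flow field
#'
#' @param case An [fvm_case()].
#' @param state A `field_state` with converged face fluxes.
#' @param source_on Deposit the irradiance source?  Default `TRUE`.
#' @param system,psolve Optional pre-assembled energy system and
#'   preconditioner application, reused across solves that share a flow
#'   field (e.g. an irradiance sweep).
#' @param scheme Convection scheme: `"limited"` (van Leer deferred
#'   correction, default) or `"upwind"`.
#' @param max_correction Cap on deferred-correction iterations.
#' @return The state with the steady temperature field filled in.
#' @export
solve_energy_steady <- function(case, state, source_on = TRUE,
                                system = NULL, psolve = NULL,
                                scheme = c("limited", "upwind"),
                                max_correction = 40L) {
  scheme <- match.arg(scheme)
  sys <- if (is.null(system)) energy_system(case, state) else system
  if (is.null(psolve)) psolve <- energy_psolve(case, sys)
  rhs0 <- sys$rhs_bc + source_vector(case, source_on)
  dims <- c(case$nx, case$ny, case$nz)
  sol <- bicgstab_solve(sys$M, rhs0, psolve, x0 = as.vector(state$T),
                        rtol = 1e-12)
  Tarr <- array(sol$x, dims)
  if (scheme == "limited") {
    Tref <- default_ambient(case)
    for (it in seq_len(max_correction)) {
      corr <- ho_correction(case, state, Tarr)
      sol <- bicgstab_solve(sys$M, rhs0 + corr, psolve,
                            x0 = as.vector(Tarr), rtol = 1e-12)
      Tnew <- array(sol$x, dims)
      dmax <- max(abs(Tnew - Tarr))
      scale <- max(abs(Tarr - Tref), 1e-30)
      Tarr <- Tnew
      if (dmax < 1e-7 * scale) break
    }
  }
  state$T <- Tarr
  state
}

#' One implicit-Euler energy step
#'
#' Advances the temperature field by `config$dt` with the current face
#' fluxes frozen: implicit upwind advection, zone-wise effective
#' diffusion, and the irradiance source if `t + dt >= t_on`.  Implicit
#' Euler is unconditionally stable; a warning is emitted when the
#' advective Courant number is so large that first-order time accuracy
#' becomes doubtful.
#'
#' @param state A `field_state`.
#' @param case An [fvm_case()].
#' @param config A [solver_config()] (its `dt` is used).
#' @return The state with updated `T` and advanced clock `t`.
#' @export
energy_step <- function(state, case, config = solver_config()) {
  dt <- config$dt
  co <- courant_number(case, state, dt)
  if (co > 100)
    warning(sprintf(
      "advective Courant number %.0f; consider dt <= %.3g s for accuracy",
      co, dt * 50 / co))
  sys <- energy_system(case, state)
  storage <- as.vector(case$rho_cp * case$vol) / dt
  on <- (state$t + dt) >= case$source$t_on
  rhs <- sys$rhs_bc + source_vector(case, on) + storage * as.vector(state$T)
  if (config$energy_scheme == "limited")
    rhs <- rhs + ho_correction(case, state, state$T)
  M <- sys$M + Diagonal(x = storage)
  psolve <- energy_psolve(case, sys, storage)
  sol <- bicgstab_solve(M, rhs, psolve, x0 = as.vector(state$T),
                        rtol = 1e-12)
  state$T <- array(sol$x, c(case$nx, case$ny, case$nz))
  state$t <- state$t + dt
  state
}

courant_number <- function(case, state, dt) {
  nx <- case$nx; ny <- case$ny; nz <- case$nz
  fx <- pmax(abs(state$phi_x[1:nx, , , drop = FALSE]),
             abs(state$phi_x[2:(nx + 1), , , drop = FALSE]))
  fy <- pmax(abs(state$phi_y[, 1:ny, , drop = FALSE]),
             abs(state$phi_y[, 2:(ny + 1), , drop = FALSE]))
  fz <- pmax(abs(state$phi_z[, , 1:nz, drop = FALSE]),
             abs(state$phi_z[, , 2:(nz + 1), drop = FALSE]))
  max((fx + fy + fz) * dt / case$vol)
}

#' Steady-state energy closure audit
#'
#' Compares the absorbed irradiance power with the net rate of enthalpy
#' leaving the domain (advective outflow above ambient plus conduction
#' into fixed-temperature boundaries).  At a converged steady state the
#' two agree to the linear-solver tolerance.
#'
#' @param case An [fvm_case()].
#' @param state A steady `field_state`.
#' @return List: `absorbed_W`, `released_W`, `relative_error`.
#' @export
energy_balance <- function(case, state) {
  g <- case$geom; mat <- case$materials
  nx <- case$nx; ny <- case$ny; nz <- case$nz
  rcp <- mat$rho_f * mat$cp_f
  k <- case$k_eff
  Tref <- default_ambient(case)
  out <- 0
  patchflux <- function(bcT, Tslab, kslab, A, hd, flux_in) {
    # net enthalpy out through this patch, relative to Tref
    adv <- sum(rcp * pmax(-flux_in, 0) * (Tslab - Tref)) -
      sum(rcp * pmax(flux_in, 0) *
            (if (bcT$type == "fixed_value") bcT$value - Tref else 0))
    cond <- if (bcT$type == "fixed_value")
      sum(kslab * A / hd * (Tslab - bcT$value)) else 0
    adv + cond
  }
  bcs <- case$bcs
  out <- out + patchflux(bcs$inlet$T, state$T[1, , ], k[1, , ], g$Ax_b,
                         g$hdx_lo, state$phi_x[1, , ])
  out <- out + patchflux(bcs$outlet$T, state$T[nx, , ], k[nx, , ], g$Ax_b,
                         g$hdx_hi, -state$phi_x[nx + 1, , ])
  out <- out + patchflux(bcs$sides$T, state$T[, 1, ], k[, 1, ], g$Ay_b,
                         g$hdy_lo, state$phi_y[, 1, ])
  out <- out + patchflux(bcs$sides$T, state$T[, ny, ], k[, ny, ], g$Ay_b,
                         g$hdy_hi, -state$phi_y[, ny + 1, ])
  out <- out + patchflux(bcs$bottom$T, state$T[, , 1], k[, , 1], g$Az_b,
                         g$hdz_lo, state$phi_z[, , 1])
  out <- out + patchflux(bcs$top$T, state$T[, , nz], k[, , nz], g$Az_b,
                         g$hdz_hi, -state$phi_z[, , nz + 1])
  absorbed <- sum(source_vector(case, TRUE))
  list(absorbed_W = absorbed, released_W = out,
       relative_error = if (absorbed > 0) abs(absorbed - out) / absorbed
       else abs(out))
}
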