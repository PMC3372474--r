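# Finite-volume discretisation of steady laminar incompressible momentum
# with Darcy-Forchheimer porous sinks, coupled by a SIMPLE pressure
# correction on a collocated grid with Rhie-Chow face interpolation.
#
# Conventions: kinematic formulation (equations divided by rho_f), so
# "pressure" is p/rho in m^2/s^2 and the porous sink per unit volume is
# -(nu*D + F/2*|U|) * U.  Face fluxes phi_* are volumetric (m^3/s),
# positive along +x/+y/+z; phi_x[i,,] is the face between cells i-1 and i.

shift_xp <- function(a) { n <- dim(a)[1]; a[c(2:n, n), , , drop = FALSE] }
shift_xm <- function(a) { n <- dim(a)[1]; a[c(1, 1:(n - 1)), , , drop = FALSE] }
shift_yp <- function(a) { n <- dim(a)[2]; a[, c(2:n, n), , drop = FALSE] }
shift_ym <- function(a) { n <- dim(a)[2]; a[, c(1, 1:(n - 1)), , drop = FALSE] }
shift_zp <- function(a) { n <- dim(a)[3]; a[, , c(2:n, n), drop = FALSE] }
shift_zm <- function(a) { n <- dim(a)[3]; a[, , c(1, 1:(n - 1)), drop = FALSE] }

# Internal-face momentum coefficients (identical for u, v, w).
momentum_internal <- function(case, st) {
  g <- case$geom; nu <- case$materials$nu
  nx <- case$nx; ny <- case$ny; nz <- case$nz
  z3 <- function() array(0, c(nx, ny, nz))
  aE <- z3(); aW <- z3(); aN <- z3(); aS <- z3(); aT <- z3(); aB <- z3()
  aP <- z3()

  De <- nu * g$Ax * g$invd_x
  Fe <- st$phi_x[2:nx, , , drop = FALSE]
  aE[1:(nx - 1), , ] <- De + pmax(-Fe, 0)
  aP[1:(nx - 1), , ] <- aP[1:(nx - 1), , ] + De + pmax(Fe, 0)
  aW[2:nx, , ] <- De + pmax(Fe, 0)
  aP[2:nx, , ] <- aP[2:nx, , ] + De + pmax(-Fe, 0)

  Dn <- nu * g$Ay * g$invd_y
  Fn <- st$phi_y[, 2:ny, , drop = FALSE]
  aN[, 1:(ny - 1), ] <- Dn + pmax(-Fn, 0)
  aP[, 1:(ny - 1), ] <- aP[, 1:(ny - 1), ] + Dn + pmax(Fn, 0)
  aS[, 2:ny, ] <- Dn + pmax(Fn, 0)
  aP[, 2:ny, ] <- aP[, 2:ny, ] + Dn + pmax(-Fn, 0)

  Dt <- nu * g$Az * g$invd_z
  Ft <- st$phi_z[, , 2:nz, drop = FALSE]
  aT[, , 1:(nz - 1)] <- Dt + pmax(-Ft, 0)
  aP[, , 1:(nz - 1)] <- aP[, , 1:(nz - 1)] + Dt + pmax(Ft, 0)
  aB[, , 2:nz] <- Dt + pmax(Ft, 0)
  aP[, , 2:nz] <- aP[, , 2:nz] + Dt + pmax(-Ft, 0)

  # porous sinks (implicit, on the diagonal)
  speed <- sqrt(st$u^2 + st$v^2 + st$w^2)
  aP <- aP + (case$nuD + 0.5 * case$Fcoef * speed) * case$vol
  list(aP = aP, aE = aE, aW = aW, aN = aN, aS = aS, aT = aT, aB = aB)
}

# Per-component boundary contributions: returns additions to aP and b.
# comp: 1 = u, 2 = v, 3 = w.  For each patch slab this computes the added
# diagonal (daP) and source (db) of the near-boundary cells:
#   fixed_value:   diffusive link nu*A/hd to the value, convective inflow
#                  carries the value, outflow stays on the diagonal;
#   no_slip:       diffusive link to 0 for every component;
#   slip:          diffusive link to 0 for the normal component only;
#   zero_gradient: upwind outflow at the cell value.
momentum_boundary_slab <- function(bc, comp, axis, nu, A, hd, flux_in,
                                   val = NULL) {
  daP <- 0 * flux_in; db <- 0 * flux_in
  if (bc$type == "fixed_value") {
    if (is.null(val)) val <- bc$value[comp]
    Db <- nu * A / hd
    daP <- Db + pmax(-flux_in, 0)
    db <- (Db + pmax(flux_in, 0)) * val
  } else if (bc$type == "no_slip") {
    daP <- daP + nu * A / hd
  } else if (bc$type == "slip") {
    if (comp == axis) daP <- daP + nu * A / hd
  } else if (bc$type == "zero_gradient") {
    daP <- pmax(-flux_in, 0)
  } else stop("unknown velocity BC type: ", bc$type)
  list(daP = daP, db = db)
}

momentum_boundary <- function(case, st, comp) {
  g <- case$geom; nu <- case$materials$nu; bcs <- case$bcs
  nx <- case$nx; ny <- case$ny; nz <- case$nz
  daP <- array(0, c(nx, ny, nz)); b <- array(0, c(nx, ny, nz))

  r <- momentum_boundary_slab(bcs$inlet$U, comp, 1L, nu, g$Ax_b, g$hdx_lo,
                              st$phi_x[1, , ])
  daP[1, , ] <- daP[1, , ] + r$daP; b[1, , ] <- b[1, , ] + r$db
  r <- momentum_boundary_slab(bcs$outlet$U, comp, 1L, nu, g$Ax_b, g$hdx_hi,
                              -st$phi_x[nx + 1, , ])
  daP[nx, , ] <- daP[nx, , ] + r$daP; b[nx, , ] <- b[nx, , ] + r$db
  r <- momentum_boundary_slab(bcs$sides$U, comp, 2L, nu, g$Ay_b, g$hdy_lo,
                              st$phi_y[, 1, ])
  daP[, 1, ] <- daP[, 1, ] + r$daP; b[, 1, ] <- b[, 1, ] + r$db
  r <- momentum_boundary_slab(bcs$sides$U, comp, 2L, nu, g$Ay_b, g$hdy_hi,
                              -st$phi_y[, ny + 1, ])
  daP[, ny, ] <- daP[, ny, ] + r$daP; b[, ny, ] <- b[, ny, ] + r$db
  bval <- if (bcs$bottom$U$type == "fixed_value" && comp == 3L)
    bcs$bottom$U$value[3] * case$bottom_open else NULL
  r <- momentum_boundary_slab(bcs$bottom$U, comp, 3L, nu, g$Az_b, g$hdz_lo,
                              st$phi_z[, , 1], val = bval)
  daP[, , 1] <- daP[, , 1] + r$daP; b[, , 1] <- b[, , 1] + r$db
  r <- momentum_boundary_slab(bcs$top$U, comp, 3L, nu, g$Az_b, g$hdz_hi,
                              -st$phi_z[, , nz + 1])
  daP[, , nz] <- daP[, , nz] + r$daP; b[, , nz] <- b[, , nz] + r$db
  list(daP = daP, b = b)
}

# Cell-centred pressure gradient with boundary faces taking the fixed
# value on fixed-pressure patches and the cell value elsewhere.
pressure_gradient <- function(case, p, fixed_zero = FALSE) {
  g <- case$geom; bcs <- case$bcs
  nx <- case$nx; ny <- case$ny; nz <- case$nz
  mesh <- case$mesh
  pfx <- array(0, c(nx + 1, ny, nz))
  pfy <- array(0, c(nx, ny + 1, nz))
  pfz <- array(0, c(nx, ny, nz + 1))
  pfx[2:nx, , ] <- (1 - g$wx) * p[1:(nx - 1), , ] + g$wx * p[2:nx, , ]
  pfy[, 2:ny, ] <- (1 - g$wy) * p[, 1:(ny - 1), ] + g$wy * p[, 2:ny, ]
  pfz[, , 2:nz] <- (1 - g$wz) * p[, , 1:(nz - 1)] + g$wz * p[, , 2:nz]
  bval <- function(patch) {
    if (bcs[[patch]]$p$type == "fixed_value") {
      if (fixed_zero) 0 else bcs[[patch]]$p$value
    } else NA
  }
  v <- bval("inlet");  pfx[1, , ]      <- if (is.na(v)) p[1, , ] else v
  v <- bval("outlet"); pfx[nx + 1, , ] <- if (is.na(v)) p[nx, , ] else v
  v <- bval("sides");  pfy[, 1, ]      <- if (is.na(v)) p[, 1, ] else v
  pfy[, ny + 1, ] <- if (is.na(v)) p[, ny, ] else v
  v <- bval("bottom"); pfz[, , 1]      <- if (is.na(v)) p[, , 1] else v
  v <- bval("top");    pfz[, , nz + 1] <- if (is.na(v)) p[, , nz] else v
  dxa <- outer(mesh$dx, matrix(1, ny, nz))
  dya <- aperm(outer(mesh$dy, matrix(1, nx, nz)), c(2, 1, 3))
  dza <- aperm(outer(mesh$dz, matrix(1, nx, ny)), c(2, 3, 1))
  list(
    gx = (pfx[2:(nx + 1), , , drop = FALSE] -
            pfx[1:nx, , , drop = FALSE]) / dxa,
    gy = (pfy[, 2:(ny + 1), , drop = FALSE] -
            pfy[, 1:ny, , drop = FALSE]) / dya,
    gz = (pfz[, , 2:(nz + 1), drop = FALSE] -
            pfz[, , 1:nz, drop = FALSE]) / dza
  )
}

# Relaxed damped-Jacobi solve of one momentum component.
jacobi_solve <- function(coef, daP, b, u0, urf, n_sweeps) {
  aP_r <- (coef$aP + daP) / urf
  b_r <- b + (1 - urf) * aP_r * u0
  u <- u0
  for (s in seq_len(n_sweeps)) {
    nb <- coef$aE * shift_xp(u) + coef$aW * shift_xm(u) +
      coef$aN * shift_yp(u) + coef$aS * shift_ym(u) +
      coef$aT * shift_zp(u) + coef$aB * shift_zm(u)
    u <- (b_r + nb) / aP_r
  }
  list(u = u, aP_r = aP_r)
}

# Normalised L1 residual of the unrelaxed momentum equation.
momentum_residual <- function(coef, daP, b, u) {
  nb <- coef$aE * shift_xp(u) + coef$aW * shift_xm(u) +
    coef$aN * shift_yp(u) + coef$aS * shift_ym(u) +
    coef$aT * shift_zp(u) + coef$aB * shift_zm(u)
  r <- (coef$aP + daP) * u - nb - b
  den <- sum(abs((coef$aP + daP) * u)) + sum(abs(b))
  if (den < 1e-300) return(0)
  sum(abs(r)) / den
}

# Sparsity pattern and index caches for the 7-point systems.
pressure_pattern <- function(nx, ny, nz) {
  ncell <- nx * ny * nz
  id <- array(seq_len(ncell), c(nx, ny, nz))
  ixP <- as.vector(id[1:(nx - 1), , ]); ixE <- as.vector(id[2:nx, , ])
  iyP <- as.vector(id[, 1:(ny - 1), ]); iyN <- as.vector(id[, 2:ny, ])
  izP <- as.vector(id[, , 1:(nz - 1)]); izT <- as.vector(id[, , 2:nz])
  list(ncell = ncell, id = id,
       i = c(ixP, ixE, iyP, iyN, izP, izT, seq_len(ncell)),
       j = c(ixE, ixP, iyN, iyP, izT, izP, seq_len(ncell)),
       ixP = ixP, ixE = ixE, iyP = iyP, iyN = iyN, izP = izP, izT = izT)
}

# One SIMPLE outer iteration.  `env` caches the pressure pattern and the
# CHOLMOD symbolic factorisation between iterations.
simple_iteration <- function(case, st, cfg, env) {
  g <- case$geom
  nx <- case$nx; ny <- case$ny; nz <- case$nz

  coef <- momentum_internal(case, st)
  bcu <- momentum_boundary(case, st, 1L)
  bcv <- momentum_boundary(case, st, 2L)
  bcw <- momentum_boundary(case, st, 3L)
  gp <- pressure_gradient(case, st$p)
  bu <- bcu$b - gp$gx * case$vol
  bv <- bcv$b - gp$gy * case$vol
  bw <- bcw$b - gp$gz * case$vol
  if (identical(cfg$momentum_scheme, "limited")) {
    # deferred-correction limited convection of momentum (carrier = 1:
    # volumetric face fluxes)
    dims <- c(nx, ny, nz)
    bu <- bu + array(ho_correction(case, st, st$u, carrier = 1), dims)
    bv <- bv + array(ho_correction(case, st, st$v, carrier = 1), dims)
    bw <- bw + array(ho_correction(case, st, st$w, carrier = 1), dims)
  }

  res_u <- momentum_residual(coef, bcu$daP, bu, st$u)
  res_v <- momentum_residual(coef, bcv$daP, bv, st$v)
  res_w <- momentum_residual(coef, bcw$daP, bw, st$w)

  su <- jacobi_solve(coef, bcu$daP, bu, st$u, cfg$urf_u, cfg$n_sweeps)
  sv <- jacobi_solve(coef, bcv$daP, bv, st$v, cfg$urf_u, cfg$n_sweeps)
  sw <- jacobi_solve(coef, bcw$daP, bw, st$w, cfg$urf_u, cfg$n_sweeps)
  st$u <- su$u; st$v <- sv$u; st$w <- sw$u

  du <- case$vol / su$aP_r
  dv <- case$vol / sv$aP_r
  dw <- case$vol / sw$aP_r

  # Rhie-Chow face fluxes on internal faces
  gp <- pressure_gradient(case, st$p)
  ubar <- (1 - g$wx) * st$u[1:(nx - 1), , , drop = FALSE] +
    g$wx * st$u[2:nx, , , drop = FALSE]
  dfx <- (1 - g$wx) * du[1:(nx - 1), , , drop = FALSE] +
    g$wx * du[2:nx, , , drop = FALSE]
  gbx <- (1 - g$wx) * gp$gx[1:(nx - 1), , , drop = FALSE] +
    g$wx * gp$gx[2:nx, , , drop = FALSE]
  st$phi_x[2:nx, , ] <- g$Ax * (ubar - dfx *
    ((st$p[2:nx, , , drop = FALSE] - st$p[1:(nx - 1), , , drop = FALSE]) *
       g$invd_x - gbx))

  vbar <- (1 - g$wy) * st$v[, 1:(ny - 1), , drop = FALSE] +
    g$wy * st$v[, 2:ny, , drop = FALSE]
  dfy <- (1 - g$wy) * dv[, 1:(ny - 1), , drop = FALSE] +
    g$wy * dv[, 2:ny, , drop = FALSE]
  gby <- (1 - g$wy) * gp$gy[, 1:(ny - 1), , drop = FALSE] +
    g$wy * gp$gy[, 2:ny, , drop = FALSE]
  st$phi_y[, 2:ny, ] <- g$Ay * (vbar - dfy *
    ((st$p[, 2:ny, , drop = FALSE] - st$p[, 1:(ny - 1), , drop = FALSE]) *
       g$invd_y - gby))

  wbar <- (1 - g$wz) * st$w[, , 1:(nz - 1), drop = FALSE] +
    g$wz * st$w[, , 2:nz, drop = FALSE]
  dfz <- (1 - g$wz) * dw[, , 1:(nz - 1), drop = FALSE] +
    g$wz * dw[, , 2:nz, drop = FALSE]
  gbz <- (1 - g$wz) * gp$gz[, , 1:(nz - 1), drop = FALSE] +
    g$wz * gp$gz[, , 2:nz, drop = FALSE]
  st$phi_z[, , 2:nz] <- g$Az * (wbar - dfz *
    ((st$p[, , 2:nz, drop = FALSE] - st$p[, , 1:(nz - 1), drop = FALSE]) *
       g$invd_z - gbz))

  st <- apply_boundary_fluxes(case, st)

  # pressure-correction coefficients
  Ex <- dfx * g$Ax * g$invd_x
  Ey <- dfy * g$Ay * g$invd_y
  Ez <- dfz * g$Az * g$invd_z
  pat <- case$pat
  diagv <- numeric(pat$ncell)
  ex <- as.vector(Ex); ey <- as.vector(Ey); ez <- as.vector(Ez)
  diagv[pat$ixP] <- diagv[pat$ixP] + ex
  diagv[pat$ixE] <- diagv[pat$ixE] + ex
  diagv[pat$iyP] <- diagv[pat$iyP] + ey
  diagv[pat$iyN] <- diagv[pat$iyN] + ey
  diagv[pat$izP] <- diagv[pat$izP] + ez
  diagv[pat$izT] <- diagv[pat$izT] + ez

  # fixed-pressure boundary faces (the pressure reference)
  bEx_hi <- bEx_lo <- bEy <- bEz <- NULL
  bcs <- case$bcs
  if (bcs$outlet$p$type == "fixed_value") {
    bEx_hi <- (du[nx, , ]) * g$Ax_b / g$hdx_hi
    diagv[pat$id[nx, , ]] <- diagv[pat$id[nx, , ]] + as.vector(bEx_hi)
  }
  if (bcs$inlet$p$type == "fixed_value") {
    bEx_lo <- (du[1, , ]) * g$Ax_b / g$hdx_lo
    diagv[pat$id[1, , ]] <- diagv[pat$id[1, , ]] + as.vector(bEx_lo)
  }
  if (is.null(bEx_hi) && is.null(bEx_lo))
    stop("no fixed-pressure patch: the pressure level is undetermined")

  M <- sparseMatrix(i = pat$i, j = pat$j,
                            x = c(-ex, -ex, -ey, -ey, -ez, -ez, diagv),
                            dims = c(pat$ncell, pat$ncell))
  Msym <- forceSymmetric(M)
  div <- (st$phi_x[2:(nx + 1), , , drop = FALSE] -
            st$phi_x[1:nx, , , drop = FALSE]) +
    (st$phi_y[, 2:(ny + 1), , drop = FALSE] -
       st$phi_y[, 1:ny, , drop = FALSE]) +
    (st$phi_z[, , 2:(nz + 1), drop = FALSE] -
       st$phi_z[, , 1:nz, drop = FALSE])
  rhs <- -as.vector(div)
  # The preconditioner factor is refreshed only when PCG has to work too
  # hard; the d-coefficients stabilise quickly, so a slightly stale
  # factor still yields an (iteratively) exact pressure solve.
  if (is.null(env$chol) || isTRUE(env$refresh)) {
    env$chol <- chol_factor(Msym)
    env$refresh <- FALSE
  }
  sol <- pcg_solve(Msym, rhs, chol_psolve(env$chol), rtol = 1e-12)
  if (sol$its >= 12L) env$refresh <- TRUE
  if (sol$rel > 1e-8) {
    env$chol <- chol_factor(Msym)
    sol <- pcg_solve(Msym, rhs, chol_psolve(env$chol), rtol = 1e-12)
  }
  pc <- array(sol$x, c(nx, ny, nz))

  # flux, pressure and velocity corrections
  st$phi_x[2:nx, , ] <- st$phi_x[2:nx, , ] -
    Ex * (pc[2:nx, , , drop = FALSE] - pc[1:(nx - 1), , , drop = FALSE])
  st$phi_y[, 2:ny, ] <- st$phi_y[, 2:ny, ] -
    Ey * (pc[, 2:ny, , drop = FALSE] - pc[, 1:(ny - 1), , drop = FALSE])
  st$phi_z[, , 2:nz] <- st$phi_z[, , 2:nz] -
    Ez * (pc[, , 2:nz, drop = FALSE] - pc[, , 1:(nz - 1), drop = FALSE])
  if (!is.null(bEx_hi))
    st$phi_x[nx + 1, , ] <- st$phi_x[nx + 1, , ] + bEx_hi * pc[nx, , ]
  if (!is.null(bEx_lo))
    st$phi_x[1, , ] <- st$phi_x[1, , ] - bEx_lo * pc[1, , ]

  gpc <- pressure_gradient(case, pc, fixed_zero = TRUE)
  st$u <- st$u - du * gpc$gx
  st$v <- st$v - dv * gpc$gy
  st$w <- st$w - dw * gpc$gz
  st$p <- st$p + cfg$urf_p * pc

  # continuity residual scaled by the through-flow
  qref <- max(sum(abs(st$phi_x[1, , ])) + sum(abs(st$phi_z[, , 1])), 1e-300)
  res_c <- sum(abs(div)) / qref

  list(state = st,
       res = c(u = res_u, v = res_v, w = res_w, continuity = res_c))
}

#' One SIMPLE momentum-and-continuity outer iteration
#'
#' Performs a discretised momentum predictor (upwind convection, central
#' diffusion, implicit porous sink), a pressure-correction solve and the
#' flux/velocity corrections.  Exposed for stepwise use; [solve_flow()]
#' wraps it in a convergence loop.
#'
#' @param state A `field_state` (from `init_state` or a previous call).
#' @param case An [fvm_case()].
#' @param config A [solver_config()].
#' @return List with `state` (updated) and `res` (named residuals: `u`,
#'   `v`, `w`, `continuity`).
#' @export
momentum_and_continuity_step <- function(state, case, config = solver_config()) {
  env <- new.env(parent = emptyenv())
  simple_iteration(case, state, config, env)
}

#' Solve the steady flow field by SIMPLE iteration
#'
#' Iterates momentum and pressure correction until all normalised
#' residuals fall below `config$tol` or `config$max_outer` is reached.
#'
#' @param case An [fvm_case()].
#' @param config A [solver_config()].
#' @param state Optional initial `field_state`.
#' @return List: `state` (converged fields and fluxes), `residuals`
#'   (data frame per iteration), `converged` (logical), `iterations`.
#' @export
solve_flow <- function(case, config = solver_config(), state = NULL) {
  if (is.null(state)) state <- init_state(case, T0 = default_ambient(case))
  env <- new.env(parent = emptyenv())
  hist <- vector("list", config$max_outer)
  converged <- FALSE
  for (it in seq_len(config$max_outer)) {
    out <- simple_iteration(case, state, config, env)
    state <- out$state
    hist[[it]] <- out$res
    if (config$verbose > 0 && it %% config$verbose == 0)
      message(sprintf("  iter %4d  u %.2e v %.2e w %.2e cont %.2e",
                      it, out$res[1], out$res[2], out$res[3], out$res[4]))
    if (max(out$res) < config$tol) { converged <- TRUE; break }
  }
  res_df <- as.data.frame(do.call(rbind, hist[seq_len(it)]))
  res_df$iteration <- seq_len(it)
  if (!converged)
    warning(sprintf(
      "flow not converged in %d iterations (final residual %.3e)",
      it, max(hist[[it]])))
  list(state = state, residuals = res_df, converged = converged,
       iterations = it)
}

default_ambient <- function(case) {
  tb <- case$bcs$inlet$T
  if (tb$type == "fixed_value") tb$value else 26
}

#' Cell-wise continuity defect of a state
#'
#' @param case An [fvm_case()].
#' @param state A `field_state` with face fluxes.
#' @return 3-D array of net volumetric outflow per cell (m^3/s).
#' @export
continuity_defect <- function(case, state) {
  nx <- case$nx; ny <- case$ny; nz <- case$nz
  (state$phi_x[2:(nx + 1), , , drop = FALSE] -
     state$phi_x[1:nx, , , drop = FALSE]) +
    (state$phi_y[, 2:(ny + 1), , drop = FALSE] -
       state$phi_y[, 1:ny, , drop = FALSE]) +
    (state$phi_z[, , 2:(nz + 1), drop = FALSE] -
       state$phi_z[, , 1:nz, drop = FALSE])
}
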