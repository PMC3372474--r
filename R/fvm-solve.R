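#' Steady conjugate solution: flow by SIMPLE, then energy
#'
#' The temperature field does not feed back on the flow (buoyancy is
#' neglected at chamber scale), so the steady problem is solved
#' segregated: SIMPLE iteration of momentum and continuity to
#' convergence, then one sparse direct solve of the energy equation on
#' the converged fluxes.
#'
#' @param case An [fvm_case()], or the pieces to build one.
#' @param config A [solver_config()].
#' @param flow Optional pre-solved flow result from [solve_flow()] (reused
#'   across irradiance levels, which do not alter the flow).
#' @return List of class `steady_solution`: `state`, `residuals`,
#'   `converged`, `balance` (energy-closure audit), `warming`
#'   (mean/max surface warming when the mesh holds a coral).
#' @export
solve_steady <- function(case, config = solver_config(), flow = NULL) {
  stopifnot(inherits(case, "fvm_case"))
  if (is.null(flow)) flow <- solve_flow(case, config)
  state <- solve_energy_steady(case, flow$state,
                               scheme = config$energy_scheme)
  out <- list(state = state, residuals = flow$residuals,
              converged = flow$converged,
              balance = energy_balance(case, state))
  if (case$has_coral) out$warming <- surface_warming(state, case)
  class(out) <- "steady_solution"
  out
}

#' @exportS3Method
print.steady_solution <- function(x, ...) {
  cat(sprintf("<steady_solution> %s after %d iterations\n",
              if (x$converged) "converged" else "NOT converged",
              nrow(x$residuals)))
  if (!is.null(x$warming))
    cat(sprintf("  surface warming: mean %.3f K, max %.3f K\n",
                x$warming["mean"], x$warming["max"]))
  cat(sprintf("  energy closure: %.2e relative\n",
              x$balance$relative_error))
  invisible(x)
}

#' Transient dark-light simulation
#'
#' Spins the flow up to steady state in the dark (the temperature field
#' stays at ambient while the lamp is off and all thermal boundaries sit
#' at ambient), then switches the irradiance on at `case$source$t_on` and
#' advances the energy equation with implicit Euler steps of `config$dt`
#' on the frozen flow field.  The energy matrix is factorised once and
#' reused for every step.
#'
#' The run ends at `config$end_time` if set, otherwise when the mean
#' surface warming is within 1% of its (exponentially extrapolated)
#' plateau.
#'
#' @param case An [fvm_case()] whose source has `t_on > 0`.
#' @param config A [solver_config()].
#' @param flow Optional pre-solved [solve_flow()] result.
#' @param max_time Hard cap on simulated time when running to plateau, s.
#' @return List of class `transient_solution`: `series` (data frame
#'   `t_s`, `dT_mean_K`, `dT_max_K`), `state` (final), `flow_residuals`.
#' @export
solve_transient <- function(case, config = solver_config(), flow = NULL,
                            max_time = 7200) {
  stopifnot(inherits(case, "fvm_case"))
  if (!case$has_coral) stop("transient warming runs need a coral mesh")
  if (is.null(flow)) flow <- solve_flow(case, config)
  st <- flow$state
  dt <- config$dt
  t_on <- case$source$t_on
  Tref <- default_ambient(case)

  sys <- energy_system(case, st)
  storage <- as.vector(case$rho_cp * case$vol) / dt
  M <- sys$M + Diagonal(x = storage)
  psolve <- energy_psolve(case, sys, storage)
  src <- source_vector(case, TRUE)
  limited <- config$energy_scheme == "limited"
  dims <- c(case$nx, case$ny, case$nz)

  n_dark <- floor(t_on / dt)
  t_end <- config$end_time
  max_steps <- if (is.na(t_end)) ceiling(max_time / dt)
    else ceiling(t_end / dt)
  ts <- numeric(0); dTm <- numeric(0); dTx <- numeric(0)
  # dark interval: all thermal boundaries at ambient and no source keep
  # T = ambient exactly; record it without stepping
  if (n_dark > 0) {
    ts <- seq(0, by = dt, length.out = n_dark)
    dTm <- numeric(n_dark); dTx <- numeric(n_dark)
  }
  Tvec <- as.vector(st$T)
  tt <- n_dark * dt
  step <- n_dark
  w_area <- case$surf_area / sum(case$surf_area)
  repeat {
    step <- step + 1L
    tt <- tt + dt
    on <- tt >= t_on
    rhs <- sys$rhs_bc + (if (on) src else 0) + storage * Tvec
    if (limited)
      rhs <- rhs + ho_correction(case, st, array(Tvec, dims))
    Tvec <- bicgstab_solve(M, rhs, psolve, x0 = Tvec, rtol = 1e-11)$x
    dsurf <- Tvec[case$surf_idx] - Tref
    ts <- c(ts, tt)
    dTm <- c(dTm, sum(w_area * dsurf))
    dTx <- c(dTx, max(dsurf))
    if (!is.na(t_end) && tt >= t_end) break
    if (is.na(t_end) && plateau_reached(ts, dTm, t_on)) break
    if (step >= max_steps) {
      if (is.na(t_end))
        warning("transient run stopped at the time cap before plateauing")
      break
    }
  }
  st$T <- array(Tvec, c(case$nx, case$ny, case$nz))
  st$t <- tt
  structure(
    list(series = data.frame(t_s = ts, dT_mean_K = dTm, dT_max_K = dTx),
         state = st, flow_residuals = flow$residuals,
         flow_converged = flow$converged),
    class = "transient_solution")
}

# Plateau detection: warming has been rising for a while and the gain
# over the trailing 30 samples is below 0.3% of the current level
# (within 1% of the exponential plateau for any tau > ~30 samples).
plateau_reached <- function(ts, dTm, t_on) {
  n <- length(ts)
  if (n < 60 || ts[n] < t_on + 120) return(FALSE)
  cur <- dTm[n]
  if (cur <= 0) return(FALSE)
  gain <- cur - dTm[n - 30L]
  gain / cur < 0.003
}

#' @exportS3Method
print.transient_solution <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf(
    "<transient_solution> %d samples to t = %.0f s; final warming %.3f K (mean), %.3f K (max)\n",
    n, x$series$t_s[n], x$series$dT_mean_K[n], x$series$dT_max_K[n]))
  invisible(x)
}
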