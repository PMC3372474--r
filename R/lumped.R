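#' Lumped heat-balance description of a coral
#'
#' Collects the quantities the closed-form heat balance needs: total
#' convective area A, irradiated (horizontally projected) area A_p, volume
#' V, the ratio S = A/V, tissue absorptivity and the effective volumetric
#' heat capacity of the porous colony.
#'
#' @param coral A [coral_shape()].
#' @param alpha Tissue absorptivity in `[0, 1]` (measured range for the
#'   validation species: 0.13-0.28).
#' @param eff An [effective_props()] for the colony-average porosity.
#' @return An object of class `lumped_coral`.
#' @export
lumped_coral <- function(coral, alpha, eff) {
  stopifnot(inherits(coral, "coral_shape"), inherits(eff, "effective_props"))
  if (alpha < 0 || alpha > 1) stop("absorptivity must lie in [0, 1]")
  A <- surface_area(coral); V <- volume(coral); Ap <- projected_area(coral)
  stopifnot(Ap <= A + 1e-12)
  structure(
    list(coral = coral, A = A, A_p = Ap, V = V, S = A / V,
         alpha = alpha, rho_cp_eff = eff$rho_cp_eff),
    class = "lumped_coral"
  )
}

#' Steady surface warming from the lumped heat balance
#'
#' At steady state the absorbed shortwave power equals the convective loss
#' (Newton's law of cooling): `alpha * I * A_p = h * A * dT`, so the
#' steady warming above ambient is `dT_ss = alpha * I * A_p / (h * A)`.
#' Warming is linear in irradiance and in absorptivity.
#'
#' @param alpha Tissue absorptivity.
#' @param I Irradiance, W/m^2.
#' @param h Convective heat-transfer coefficient, W/(m^2 K).
#' @param A_p Irradiated (projected) area, m^2.
#' @param A Total convective surface area, m^2.
#' @return Steady warming above ambient, K.
#' @examples
#' steady_warming(0.2, 600, 200, A_p = 1, A = 3)  # 0.2 K
#' @export
steady_warming <- function(alpha, I, h, A_p, A) {
  if (any(h <= 0)) stop("heat-transfer coefficient must be > 0")
  if (any(I < 0)) stop("irradiance must be >= 0")
  stopifnot(alpha >= 0, alpha <= 1, A_p > 0, A > 0)
  alpha * I * A_p / (h * A)
}

#' Thermal time constant of a coral
#'
#' The first-order heat balance `rhoCp_eff V dT/dt = Q_in - h A dT` has the
#' e-folding time `tau = rhoCp_eff / (h S)` with `S = A/V`: tau grows with
#' volume (thermal mass) and falls with surface area and with stronger
#' convection.  Branching corals (large S) respond much faster than
#' massive ones.
#'
#' @param rho_cp_eff Effective volumetric heat capacity, J/(m^3 K).
#' @param h Heat-transfer coefficient, W/(m^2 K).
#' @param S Surface-to-volume ratio, 1/m.
#' @return Time constant, s.
#' @examples
#' time_constant(4.0e6, 200, 257)  # ~77.8 s
#' @export
time_constant <- function(rho_cp_eff, h, S) {
  if (any(h <= 0) || any(S <= 0)) stop("h and S must be > 0")
  stopifnot(rho_cp_eff > 0)
  rho_cp_eff / (h * S)
}

#' Exponential dark-light warming trajectory
#'
#' Under constant irradiance switched on at `t_on`, the lumped balance
#' warms as `dT(t) = dT_ss * (1 - exp(-(t - t_on)/tau))` for `t >= t_on`
#' and stays at 0 before.
#'
#' @param dT_ss Steady warming, K.
#' @param tau Time constant, s.
#' @param t_on Illumination onset, s.
#' @return A function of time `t` (vectorised) returning warming in K.
#' @export
transient_warming <- function(dT_ss, tau, t_on = 0) {
  if (tau <= 0) stop("tau must be > 0")
  force(dT_ss); force(t_on)
  function(t) ifelse(t < t_on, 0, dT_ss * (1 - exp(-(t - t_on) / tau)))
}

#' Forced-convection heat-transfer coefficient from a Nusselt correlation
#'
#' Closes the lumped model with a laminar forced-convection correlation:
#' the Whitaker sphere form for hemispherical corals,
#' `Nu = 2 + (0.4 Re^0.5 + 0.06 Re^(2/3)) Pr^0.4`,
#' and the Churchill-Bernstein cylinder-in-crossflow form for branches.
#' Then `h = Nu k_f / d`.  These unbounded-flow correlations are indicative
#' only: the emergent heat-transfer coefficient of a coral on the chamber
#' floor, with a porous interior and a conducting base, can differ
#' substantially (which is why the finite-volume model exists).
#'
#' @param Re Reynolds number `U d / nu`.
#' @param Pr Prandtl number.
#' @param d Body diameter, m.
#' @param shape `"hemisphere"` (sphere-form) or `"cylinder"` (crossflow).
#' @param k_f Fluid conductivity, W/(m K).
#' @return List with `h` (W/(m^2 K)), `Nu` and the correlation name.
#' @export
h_from_correlation <- function(Re, Pr, d,
                               shape = c("hemisphere", "cylinder"),
                               k_f = 0.61) {
  shape <- match.arg(shape)
  stopifnot(Re >= 0, Pr > 0, d > 0)
  if (Re > 500)
    warning("Re outside the laminar range the correlation was chosen for")
  if (shape == "hemisphere") {
    Nu <- 2 + (0.4 * sqrt(Re) + 0.06 * Re^(2 / 3)) * Pr^0.4
    corr <- "Whitaker (sphere)"
  } else {
    Nu <- 0.3 + (0.62 * sqrt(Re) * Pr^(1 / 3)) /
      (1 + (0.4 / Pr)^(2 / 3))^0.25 *
      (1 + (Re / 282000)^(5 / 8))^(4 / 5)
    corr <- "Churchill-Bernstein (cylinder)"
  }
  list(h = Nu * k_f / d, Nu = Nu, correlation = corr)
}

#' Run the lumped model end to end
#'
#' Convenience wrapper: computes Re, Pr, h (from the chosen correlation),
#' the steady warming, time constant and a sampled warming trajectory.
#'
#' @param coral A [coral_shape()].
#' @param alpha Tissue absorptivity.
#' @param phi Colony porosity used for the effective heat capacity.
#' @param I Irradiance, W/m^2.
#' @param U Free-stream speed, m/s.
#' @param t_on Illumination onset, s.
#' @param t_end End of the sampled trajectory, s (default `t_on + 6 tau`).
#' @param mat A [material_set()].
#' @return List with `summary` (one-row data frame: dT_ss, tau, h, Re, Pr)
#'   and `series` (data frame `t_s`, `dT_K`).
#' @export
lumped_response <- function(coral, alpha, phi, I, U, t_on = 0,
                            t_end = NULL, mat = material_set()) {
  eff <- effective_props(phi, mat)
  lc <- lumped_coral(coral, alpha, eff)
  d <- 2 * coral$radius
  Re <- U * d / mat$nu
  Pr <- prandtl_number(mat$nu, mat$alpha_f)
  hh <- h_from_correlation(Re, Pr, d, coral$kind, mat$k_f)
  dT_ss <- steady_warming(alpha, I, hh$h, lc$A_p, lc$A)
  tau <- time_constant(eff$rho_cp_eff, hh$h, lc$S)
  if (is.null(t_end)) t_end <- t_on + 6 * tau
  tt <- seq(0, t_end, by = max(1, round(t_end / 2000)))
  traj <- transient_warming(dT_ss, tau, t_on)
  list(
    summary = data.frame(dT_ss_K = dT_ss, tau_s = tau, h = hh$h,
                         Nu = hh$Nu, Re = Re, Pr = Pr,
                         correlation = hh$correlation),
    series = data.frame(t_s = tt, dT_K = traj(tt))
  )
}
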