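#' Fluid and coral constituent properties
#'
#' Default values describe seawater at 26 C and the aragonite skeleton
#' (calcium-carbonate polymorph, true density 2.94 g/cm^3).  The
#' symbol set distinguishes the fluid (rho_f, Cp_f, k_f, mu) from the coral
#' solid (rho_c, Cp_c, k_c); the solid heat capacity and conductivity use
#' standard mineral-table values for aragonite/calcite.
#'
#' @param rho_f Fluid density, kg/m^3.
#' @param cp_f Fluid specific heat, J/(kg K).
#' @param k_f Fluid thermal conductivity, W/(m K).
#' @param mu Fluid dynamic viscosity, Pa s.
#' @param rho_c Coral solid density, kg/m^3.
#' @param cp_c Coral solid specific heat, J/(kg K).
#' @param k_c Coral solid thermal conductivity, W/(m K).
#' @return An object of class `material_set`, including the kinematic
#'   viscosity `nu = mu/rho_f` and fluid thermal diffusivity `alpha_f`.
#' @export
material_set <- function(rho_f = 996.8, cp_f = 4179, k_f = 0.61,
                         mu = 8.7e-4,
                         rho_c = 2940, cp_c = 880, k_c = 2.2) {
  vals <- c(rho_f, cp_f, k_f, mu, rho_c, cp_c, k_c)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all material properties must be finite and > 0")
  structure(
    list(rho_f = rho_f, cp_f = cp_f, k_f = k_f, mu = mu,
         nu = mu / rho_f, alpha_f = k_f / (rho_f * cp_f),
         rho_c = rho_c, cp_c = cp_c, k_c = k_c),
    class = "material_set"
  )
}

#' Skeletal porosity from bulk and true density
#'
#' Porosity is the void fraction of the medium: `phi = 1 - rho_b/rho_t`,
#' where `rho_b` is the oven-dry bulk density of a sectioned skeletal core
#' and `rho_t` the true (aragonite) density, 2.94 g/cm^3.
#'
#' @param rho_b Bulk density, g/cm^3 (same units as `rho_t`).
#' @param rho_t True density, g/cm^3.
#' @return Porosity in `[0, 1]`.
#' @examples
#' porosity_from_density(1.7493, 2.94)  # ~0.405, S. hystrix
#' @export
porosity_from_density <- function(rho_b, rho_t = 2.94) {
  stopifnot(is.numeric(rho_b), is.numeric(rho_t))
  if (any(rho_t <= 0)) stop("true density must be > 0")
  if (any(rho_b < 0)) stop("bulk density must be >= 0")
  if (any(rho_b > rho_t))
    stop("bulk density exceeds true density (non-physical)")
  1 - rho_b / rho_t
}

#' @rdname porosity_from_density
#' @param phi Porosity in `[0, 1]`.
#' @export
bulk_density_from_porosity <- function(phi, rho_t = 2.94) {
  stopifnot(all(phi >= 0 & phi <= 1), rho_t > 0)
  (1 - phi) * rho_t
}

#' Effective porous-medium properties under local thermal equilibrium
#'
#' The tissue and skeleton zones are porous media whose solid matrix and
#' pore water share one temperature.  Effective properties are
#' volume-weighted means of the constituents:
#' `rho_eff  = phi*rho_f + (1-phi)*rho_c`,
#' `rhoCp_eff = phi*rho_f*Cp_f + (1-phi)*rho_c*Cp_c`,
#' `k_eff = phi*k_f + (1-phi)*k_c` (arithmetic/parallel mean; a
#' harmonic/series option is available), and the effective diffusivity
#' `alpha_eff = k_eff / rhoCp_eff`.
#'
#' @param phi Porosity in `[0, 1]`.
#' @param mat A [material_set()].
#' @param k_mean `"arithmetic"` (default) or `"harmonic"` mean for the
#'   effective conductivity.
#' @return An object of class `effective_props` with fields `rho_eff`,
#'   `cp_eff`, `rho_cp_eff`, `k_eff`, `alpha_eff`.
#' @export
effective_props <- function(phi, mat = material_set(),
                            k_mean = c("arithmetic", "harmonic")) {
  k_mean <- match.arg(k_mean)
  stopifnot(inherits(mat, "material_set"))
  if (any(phi < 0 | phi > 1)) stop("porosity must lie in [0, 1]")
  rho_eff <- phi * mat$rho_f + (1 - phi) * mat$rho_c
  rho_cp_eff <- phi * mat$rho_f * mat$cp_f + (1 - phi) * mat$rho_c * mat$cp_c
  k_eff <- if (k_mean == "arithmetic") {
    phi * mat$k_f + (1 - phi) * mat$k_c
  } else {
    1 / (phi / mat$k_f + (1 - phi) / mat$k_c)
  }
  structure(
    list(phi = phi, rho_eff = rho_eff,
         cp_eff = rho_cp_eff / rho_eff, rho_cp_eff = rho_cp_eff,
         k_eff = k_eff, alpha_eff = k_eff / rho_cp_eff),
    class = "effective_props"
  )
}

#' Darcy (viscous) resistance of a porous coral zone
#'
#' Blake-Kozeny closure for viscous loss in laminar percolation:
#' `D = 150 (1-phi)^2 / (phi^3 d^2)`, contributing a momentum sink
#' `-nu D U` per unit volume.  `d` is the diameter of the coral sample
#' under investigation.
#'
#' @param phi Porosity, strictly inside (0, 1].
#' @param d Characteristic (sample) diameter, m.
#' @return Viscous resistance D in 1/m^2.
#' @examples
#' darcy_coefficient(0.475, 0.035)  # ~3.15e5
#' @export
darcy_coefficient <- function(phi, d) {
  stopifnot(d > 0)
  if (any(phi <= 0))
    stop("phi = 0 means a solid zone, not a porous one (infinite resistance)")
  if (any(phi > 1)) stop("porosity must be <= 1")
  150 * (1 - phi)^2 / (phi^3 * d^2)
}

#' Forchheimer (inertial) resistance of a porous coral zone
#'
#' Burke-Plummer closure for kinetic loss: `F = 3.5 (1-phi) / (phi^3 d)`,
#' contributing a momentum sink `-(F/2) |U| U` per unit volume.  At the
#' low percolation velocities of the validation chamber the pressure drop
#' is viscous-dominated and this term can be omitted (it is off by default
#' in the solver configuration).
#'
#' @inheritParams darcy_coefficient
#' @return Inertial resistance F in 1/m.
#' @examples
#' forchheimer_coefficient(0.5, 0.035)  # 400
#' @export
forchheimer_coefficient <- function(phi, d) {
  stopifnot(d > 0)
  if (any(phi <= 0)) stop("phi must be > 0")
  if (any(phi > 1)) stop("porosity must be <= 1")
  3.5 * (1 - phi) / (phi^3 * d)
}

#' Prandtl number
#'
#' Ratio of momentum to thermal diffusivity, `Pr = nu / alpha`; governs the
#' relative thickness of the velocity and thermal boundary layers over the
#' coral surface.
#'
#' @param nu Kinematic viscosity, m^2/s.
#' @param alpha_d Thermal diffusivity, m^2/s.
#' @return Dimensionless Prandtl number.
#' @export
prandtl_number <- function(nu, alpha_d) {
  stopifnot(nu >= 0)
  if (any(alpha_d <= 0)) stop("thermal diffusivity must be > 0")
  nu / alpha_d
}

#' Porous-zone specification
#'
#' Bundles the porosity, characteristic diameter and the derived
#' Darcy-Forchheimer resistances for one zone (tissue or skeleton).
#'
#' @param phi Zone porosity.
#' @param d Characteristic diameter (the coral sample diameter), m.
#' @param use_forchheimer Keep the inertial term?  Default `FALSE` (omitted
#'   at low percolation velocities).
#' @return An object of class `porous_zone_spec` with `phi`, `d`, `D`, `F`.
#' @export
porous_zone_spec <- function(phi, d, use_forchheimer = FALSE) {
  D <- darcy_coefficient(phi, d)
  F <- if (use_forchheimer) forchheimer_coefficient(phi, d) else 0
  structure(list(phi = phi, d = d, D = D, F = F,
                 use_forchheimer = use_forchheimer),
            class = "porous_zone_spec")
}
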