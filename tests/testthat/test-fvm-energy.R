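# Energy-equation verification: conduction oracle, conservation audits,
# source handling.

test_that("1-D transient conduction matches the analytic series within 1%", {
  # water slab of height L, insulated everywhere except the thermostatted
  # floor; uniform initial excess temperature decays by pure conduction
  dom <- chamber_domain(length = 0.05, width = 0.01, height = 0.02)
  m <- build_mesh(dom, NULL, c(3, 3, 40))
  bcs <- boundary_set(U_inlet = 0, bottom_mode = "no_slip", T_value = 26)
  bcs$inlet$T <- list(type = "zero_gradient")   # keep the slab 1-D
  case <- fvm_case(m, bcs = bcs)
  st <- coraltherm:::init_state(case)
  st$T[] <- 30
  dt <- 2; nsteps <- 300
  cfg <- solver_config(dt = dt)
  for (s in seq_len(nsteps)) st <- energy_step(st, case, cfg)
  tend <- dt * nsteps
  mat <- material_set()
  L <- dom$height
  series_T <- function(z, t) {
    n <- 0:60
    lam <- (2 * n + 1) * pi / (2 * L)
    4 / pi * sum(1 / (2 * n + 1) *
                   sin(lam * z) * exp(-lam^2 * mat$alpha_f * t))
  }
  Tnum <- st$T[2, 2, ]
  Tana <- 26 + 4 * vapply(m$z, series_T, 1, t = tend)
  expect_lt(max(abs(Tnum - Tana)) / 4, 0.01)
})

test_that("zero irradiance keeps the chamber isothermal to machine precision", {
  coral <- coral_shape("hemisphere", 0.0175)
  m <- build_mesh(chamber_domain(), coral, c(32, 18, 18))
  porous <- list(tissue = porous_zone_spec(0.05, 0.035),
                 skeleton = porous_zone_spec(0.475, 0.035))
  case <- fvm_case(m, porous = porous, source = irradiance_source(0, 0.2))
  fl <- solve_flow(case, solver_config(max_outer = 200, tol = 1e-5))
  sol <- solve_steady(case, flow = fl)
  expect_lt(max(abs(sol$state$T - 26)), 1e-9)
  # and one transient step in the dark does not create heat either
  st2 <- energy_step(fl$state, case, solver_config(dt = 1))
  expect_lt(max(abs(st2$T - 26)), 1e-9)
})

test_that("absorbed irradiance balances boundary losses at steady state", {
  coral <- coral_shape("hemisphere", 0.0175)
  m <- build_mesh(chamber_domain(), coral, c(32, 18, 18))
  porous <- list(tissue = porous_zone_spec(0.05, 0.035),
                 skeleton = porous_zone_spec(0.475, 0.035))
  case <- fvm_case(m, porous = porous,
                   source = irradiance_source(600, 0.2))
  sol <- solve_steady(case, solver_config(max_outer = 250, tol = 1e-5))
  expect_lt(sol$balance$relative_error, 0.01)
  # collimated beam: absorbed power is alpha * I * (zone footprint)
  footprint <- sum(apply(m$zone != 0L, c(1, 2), any) * (m$dx %o% m$dy))
  expect_equal(sol$balance$absorbed_W, 0.2 * 600 * footprint,
               tolerance = 1e-10)
  # surface-flux option: absorbed power is alpha * I * (analytic lit cap)
  case_s <- fvm_case(m, porous = porous,
                     source = irradiance_source(600, 0.2,
                                                deposition = "surface"))
  expect_equal(sum(coraltherm:::source_vector(case_s, TRUE)),
               0.2 * 600 * 2 * pi * 0.0175^2, tolerance = 1e-10)
  # warming is positive and the field never undershoots the ambient
  expect_gt(sol$warming["mean"], 0)
  expect_gt(min(sol$state$T), 26 - 1e-6)
})

test_that("surface warming responds linearly to irradiance and absorptivity", {
  coral <- coral_shape("cylinder", 0.005, 0.008)
  m <- build_mesh(chamber_domain(), coral, c(44, 26, 24))
  porous <- list(tissue = porous_zone_spec(0.05, 0.01),
                 skeleton = porous_zone_spec(0.405, 0.01))
  case <- fvm_case(m, porous = porous,
                   source = irradiance_source(600, 0.2))
  cfg <- solver_config(max_outer = 250, tol = 1e-5)
  flow <- solve_flow(case, cfg)
  w600 <- surface_warming(solve_energy_steady(case, flow$state), case)
  case$source <- irradiance_source(1200, 0.2)
  w1200 <- surface_warming(solve_energy_steady(case, flow$state), case)
  expect_equal(w1200["mean"], 2 * w600["mean"], tolerance = 1e-6)
  case$source <- irradiance_source(600, 0.4)
  wa <- surface_warming(solve_energy_steady(case, flow$state), case)
  expect_equal(wa["mean"], 2 * w600["mean"], tolerance = 1e-6)
})

test_that("surface warming statistics track the tissue surface", {
  coral <- coral_shape("hemisphere", 0.0175)
  m <- build_mesh(chamber_domain(), coral, c(32, 18, 18))
  porous <- list(tissue = porous_zone_spec(0.05, 0.035),
                 skeleton = porous_zone_spec(0.475, 0.035))
  case <- fvm_case(m, porous = porous)
  st <- coraltherm:::init_state(case)
  expect_equal(unname(surface_warming(st, case)), c(0, 0))
  # a single hot surface cell moves the max but barely the mean
  Tv <- as.vector(st$T)
  Tv[case$surf_idx[1]] <- 26.5
  st$T <- array(Tv, dim(st$T))
  w <- surface_warming(st, case)
  expect_equal(unname(w["max"]), 0.5)
  expect_lt(w["mean"], 0.05)
  # empty chamber has no surface to report on
  empty <- fvm_case(build_mesh(chamber_domain(), NULL, c(8, 4, 4)),
                    bcs = boundary_set(bottom_mode = "slip"))
  expect_error(surface_warming(st, empty), "surface")
})
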