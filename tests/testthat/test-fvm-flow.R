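# Flow-solver verification against exact and analytic solutions.

test_that("uniform inlet through an empty slip-walled chamber is exact", {
  m <- build_mesh(chamber_domain(), NULL, c(20, 8, 8))
  case <- fvm_case(m, bcs = boundary_set(U_inlet = 0.002,
                                         bottom_mode = "slip"))
  fl <- solve_flow(case, solver_config(max_outer = 30))
  expect_true(fl$converged)
  expect_lt(max(abs(fl$state$u - 0.002)), 1e-12)
  expect_lt(max(abs(fl$state$v)), 1e-12)
  expect_lt(max(abs(fl$state$w)), 1e-12)
  # discrete continuity residual at plug flow
  expect_lt(utils::tail(fl$residuals$continuity, 1), 1e-8)
})

test_that("plane-channel flow matches the Poiseuille profile within 2%", {
  dom <- chamber_domain(length = 0.1, width = 0.01, height = 0.02)
  m <- build_mesh(dom, NULL, c(30, 3, 40))
  bcs <- boundary_set(U_inlet = 0.002, bottom_mode = "no_slip",
                      top_mode = "no_slip")
  case <- fvm_case(m, materials = material_set(mu = 0.9968), bcs = bcs)
  fl <- solve_flow(case, solver_config(max_outer = 2000, tol = 1e-8))
  expect_true(fl$converged)
  uprof <- fl$state$u[28, 2, ]
  H <- dom$height
  analytic <- 6 * 0.002 * (m$z / H) * (1 - m$z / H)
  expect_lt(max(abs(uprof - analytic)) / max(analytic), 0.02)
  expect_equal(max(uprof) / (sum(uprof * m$dz) / H), 1.5, tolerance = 0.02)
})

test_that("a nearly solid coral diverts the flow around it", {
  coral <- coral_shape("hemisphere", 0.0175)
  m <- build_mesh(chamber_domain(), coral, c(32, 18, 18))
  porous <- list(tissue = porous_zone_spec(0.01, 0.035),
                 skeleton = porous_zone_spec(0.01, 0.035))
  case <- fvm_case(m, porous = porous, bcs = boundary_set())
  fl <- solve_flow(case, solver_config(max_outer = 250, tol = 1e-5))
  sp <- sqrt(fl$state$u^2 + fl$state$v^2 + fl$state$w^2)
  inside <- m$zone == 2L
  expect_lt(max(sp[inside]), 0.01 * 0.002)   # interior essentially stagnant
  # flow accelerates somewhere around the blockage
  expect_gt(max(sp[m$zone == 0L]), 0.002)
  # mass conserved cell-by-cell
  defect <- continuity_defect(case, fl$state)
  expect_lt(max(abs(defect)) / (0.002 * 0.005), 1e-10)
})

test_that("boundary conditions are applied as tabulated", {
  coral <- coral_shape("hemisphere", 0.0175)
  m <- build_mesh(chamber_domain(), coral, c(32, 18, 18))
  porous <- list(tissue = porous_zone_spec(0.05, 0.035),
                 skeleton = porous_zone_spec(0.475, 0.035))
  case <- fvm_case(m, porous = porous,
                   bcs = boundary_set(U_inlet = 0.002, U_bottom = 0.001))
  st <- apply_boundary_conditions(coraltherm:::init_state(case), case)
  expect_equal(inlet_mean_speed(case, st), 0.002)
  # impermeable top and sides
  expect_true(all(st$phi_z[, , case$nz + 1] == 0))
  expect_true(all(st$phi_y[, 1, ] == 0))
  # bed percolation enters through the open sand floor only
  open_cells <- case$bottom_open > 0
  expect_true(all(st$phi_z[, , 1][!open_cells] == 0))
  wspeed <- st$phi_z[, , 1][open_cells] / case$geom$Az_b[open_cells]
  expect_equal(unname(wspeed), rep(0.001, sum(open_cells)))
  # every patch needs a complete condition set
  broken <- case
  broken$bcs$top$T <- NULL
  expect_error(apply_boundary_conditions(st, broken), "top")
})

test_that("momentum steps report shrinking residuals on a disturbed field", {
  m <- build_mesh(chamber_domain(), NULL, c(16, 6, 6))
  case <- fvm_case(m, bcs = boundary_set(bottom_mode = "slip"))
  st <- coraltherm:::init_state(case)
  set.seed(1)
  st$u <- st$u * (1 + 0.3 * array(stats::runif(length(st$u), -1, 1),
                                  dim(st$u)))
  st <- coraltherm:::compute_fluxes_linear(case, st)
  cfg <- solver_config()
  r1 <- momentum_and_continuity_step(st, case, cfg)
  r5 <- r1
  for (i in 1:12) r5 <- momentum_and_continuity_step(r5$state, case, cfg)
  expect_lt(r5$res["u"], r1$res["u"])
  # after every pressure correction the fluxes are divergence-free
  expect_lt(max(abs(continuity_defect(case, r5$state))) / (0.002 * 0.005),
            1e-10)
})
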