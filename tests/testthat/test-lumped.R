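test_that("steady warming balances absorption against Newton cooling", {
  # Q_in = Q_out at the returned warming, exactly
  alpha <- 0.23; I <- 700; h <- 150; A_p <- 9.6e-4; A <- 2.9e-3
  dT <- steady_warming(alpha, I, h, A_p, A)
  expect_equal(alpha * I * A_p, h * A * dT)
  expect_equal(steady_warming(0.2, 600, 200, 1, 3), 0.2)
  expect_equal(steady_warming(0.2, 0, 200, 1, 3), 0)
  # linear in irradiance and absorptivity
  expect_equal(steady_warming(0.2, 1200, 200, 1, 3),
               2 * steady_warming(0.2, 600, 200, 1, 3))
  expect_equal(steady_warming(0.4, 600, 200, 1, 3),
               2 * steady_warming(0.2, 600, 200, 1, 3))
  expect_error(steady_warming(0.2, 600, 0, 1, 3), "> 0")
})

test_that("time constant scales as rhoCp/(h S)", {
  expect_equal(time_constant(4.0e6, 200, 257), 77.8, tolerance = 1e-3)
  expect_equal(time_constant(4.0e6, 200, 257 / 2),
               2 * time_constant(4.0e6, 200, 257))
  # at equal rhoCp and h, the hemisphere/branch tau ratio is the inverse
  # of the A/V ratio: 3000/180
  expect_equal(time_constant(4e6, 200, 180) / time_constant(4e6, 200, 3000),
               3000 / 180, tolerance = 1e-12)
})

test_that("transient warming is the canonical saturating exponential", {
  traj <- transient_warming(dT_ss = 0.5, tau = 300, t_on = 143)
  expect_equal(traj(100), 0)
  expect_equal(traj(143), 0)
  expect_equal(traj(143 + 300), 0.5 * (1 - exp(-1)))
  expect_equal(traj(143 + 300), 0.632 * 0.5, tolerance = 1e-3)
  expect_equal(traj(1e6), 0.5)
  tt <- seq(143, 2000, by = 7)
  expect_true(all(diff(traj(tt)) > 0))       # monotone approach from below
})

test_that("Nusselt correlations have the right limits and monotonicity", {
  # conduction limit of the sphere form
  lim <- h_from_correlation(0, 6, 0.035, "hemisphere")
  expect_equal(lim$Nu, 2)
  expect_equal(lim$h, 2 * 0.61 / 0.035)
  # chamber-scale evaluation lands in the expected range
  mid <- h_from_correlation(72, 6, 0.035, "hemisphere")
  expect_gt(mid$h, 150); expect_lt(mid$h, 250)
  # h increases with Re for both forms
  for (shape in c("hemisphere", "cylinder")) {
    hs <- vapply(c(5, 20, 80, 300),
                 function(Re) h_from_correlation(Re, 6, 0.01, shape)$h, 1)
    expect_true(all(diff(hs) > 0))
  }
  expect_warning(h_from_correlation(5000, 6, 0.035), "laminar")
})

test_that("lumped_response ties the pieces together consistently", {
  co <- coral_shape("hemisphere", 0.0175)
  res <- lumped_response(co, alpha = 0.2, phi = 0.475, I = 600, U = 0.002,
                         t_on = 100)
  s <- res$summary
  expect_equal(s$Re, 0.002 * 0.035 / material_set()$nu)
  expect_equal(s$dT_ss_K,
               steady_warming(0.2, 600, s$h, projected_area(co),
                              surface_area(co)))
  eff <- effective_props(0.475)
  expect_equal(s$tau_s, time_constant(eff$rho_cp_eff, s$h, av_ratio(co)))
  # sampled trajectory plateaus at the steady warming
  expect_equal(max(res$series$dT_K), s$dT_ss_K, tolerance = 0.01)
})

test_that("lumped coral enforces geometric sanity", {
  eff <- effective_props(0.5)
  expect_error(lumped_coral(coral_shape("hemisphere", 0.0175), 1.2, eff),
               "absorptivity")
  lc <- lumped_coral(coral_shape("hemisphere", 0.0175), 0.2, eff)
  expect_lte(lc$A_p, lc$A)
  expect_equal(lc$S, av_ratio(lc$coral))
})
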