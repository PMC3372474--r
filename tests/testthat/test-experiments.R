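test_that("the five validation species presets carry the measured values", {
  pr <- make_presets()
  expect_length(pr, 5)
  expect_setequal(names(pr),
                  c("Porites lobata", "Stylophora pistillata", "Favia sp.",
                    "Cyphastrea serailia", "Seriatopora hystrix"))
  pl <- pr[["Porites lobata"]]
  expect_equal(pl$coral$kind, "hemisphere")
  expect_equal(2 * pl$coral$radius, 0.035)
  expect_equal(pl$porosity, 0.475)
  expect_false(pl$porosity_assumed)
  sp <- pr[["Stylophora pistillata"]]
  expect_equal(sp$coral$kind, "cylinder")
  expect_equal(2 * sp$coral$radius, 0.006)
  expect_equal(sp$coral$height, 0.006)
  expect_equal(sp$porosity, 0.431)
  # massive species unavailable for coring: porosity assumed
  expect_true(pr[["Cyphastrea serailia"]]$porosity_assumed)
  expect_equal(pr[["Cyphastrea serailia"]]$porosity, 0.500)
  expect_equal(pr[["Seriatopora hystrix"]]$porosity, 0.405)
  expect_equal(pr[["Cyphastrea serailia"]]$t_on_s, 143)
  expect_equal(pr[["Seriatopora hystrix"]]$t_on_s, 235)
  expect_equal(pl$alpha_range, c(0.13, 0.28))
})

test_that("preset Reynolds numbers reproduce the tabulated flow regime", {
  pr <- make_presets()
  for (p in pr) {
    Re <- reynolds_number(0.002, 2 * p$coral$radius)
    expect_lt(abs(Re - p$Re_low) / p$Re_low, 0.15)
    if (!is.na(p$Re_high)) {
      Re_h <- reynolds_number(0.013, 2 * p$coral$radius)
      expect_lt(abs(Re_h - p$Re_high) / p$Re_high, 0.15)
    }
  }
  # every tabulated regime is laminar
  expect_lt(max(unlist(lapply(pr, function(p)
    c(p$Re_low, p$Re_high))), na.rm = TRUE), 500)
})

test_that("steady sweep reports a near-perfect linear irradiance response", {
  p <- test_branch_preset()
  sw <- run_steady_sweep(p, I_list = c(500, 650, 800, 950),
                         config = solver_config(max_outer = 300, tol = 1e-5))
  expect_equal(nrow(sw$table), 4)
  expect_true(all(diff(sw$table$dT) > 0))
  expect_gte(sw$fit$r_squared, 0.99)
  # a single-irradiance "sweep" returns the table but no fit
  sw1 <- run_steady_sweep(p, I_list = 600,
                          config = solver_config(max_outer = 300, tol = 1e-5))
  expect_null(sw1$fit)
  expect_equal(nrow(sw1$table), 1)
})

test_that("flow comparison calibrates within range and predicts a decrease", {
  tab <- run_flow_comparison(list(test_branch_preset()),
                             config = solver_config(max_outer = 300,
                                                    tol = 1e-5))
  expect_equal(nrow(tab), 1)
  expect_gte(tab$alpha, 0.13)
  expect_lte(tab$alpha, 0.28)
  expect_lt(tab$dT_high_K, tab$dT_low_K)   # high flow cools
  # when unclipped, the calibrated low-flow warming hits the target exactly
  if (!tab$alpha_clipped) expect_equal(tab$dT_low_K, tab$ref_low_K)
})

test_that("run configuration round-trips through YAML", {
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(c(
    "geometry:",
    "  shape: cylinder",
    "  diameter_mm: 10",
    "  height_mm: 8",
    "  resolution: [44, 26, 24]",
    "porous:",
    "  skeleton_phi: 0.431",
    "boundary:",
    "  U_inlet: 0.013",
    "irradiance:",
    "  I: 600",
    "  alpha: 0.25",
    "solver:",
    "  max_outer: 50"), cfg_file)
  rc <- read_run_config(cfg_file)
  expect_s3_class(rc$case, "fvm_case")
  expect_equal(rc$case$source$I, 600)
  expect_equal(rc$case$source$alpha, 0.25)
  expect_equal(rc$case$bcs$inlet$U$value[1], 0.013)
  expect_equal(rc$config$max_outer, 50)
  expect_equal(rc$case$mesh$coral$kind, "cylinder")
})

test_that("VTK export writes a readable rectilinear grid", {
  m <- build_mesh(chamber_domain(), NULL, c(8, 4, 4))
  case <- fvm_case(m, bcs = boundary_set(bottom_mode = "slip"))
  st <- coraltherm:::init_state(case)
  f <- tempfile(fileext = ".vtk")
  write_vtk(case, f, st)
  lines <- readLines(f)
  expect_equal(lines[4], "DATASET RECTILINEAR_GRID")
  expect_true(any(grepl("DIMENSIONS 9 5 5", lines)))
  expect_true(any(grepl("CELL_DATA 128", lines)))
  expect_true(any(grepl("VECTORS velocity", lines)))
})
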