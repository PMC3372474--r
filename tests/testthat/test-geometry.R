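test_that("hemisphere area/volume follow the curved-plus-base convention", {
  r <- 0.0175
  h <- coral_shape("hemisphere", radius = r)
  expect_equal(surface_area(h), 3 * pi * r^2)
  expect_equal(volume(h), (2 / 3) * pi * r^3, tolerance = 1e-12)
  expect_equal(volume(h), 1.1231e-5, tolerance = 1e-4)
  # A/V reduces to 4.5/r for every radius
  for (rr in c(0.001, 0.0175, 0.025, 0.1)) {
    co <- coral_shape("hemisphere", rr, tissue_thickness = rr / 10)
    expect_equal(av_ratio(co) * rr, 4.5)
  }
})

test_that("cylinder area/volume follow the standard convention", {
  cy <- coral_shape("cylinder", radius = 0.003, height = 0.006)
  expect_equal(volume(cy), pi * 0.003^2 * 0.006)
  expect_equal(volume(cy), 1.696e-7, tolerance = 1e-3)
  expect_equal(av_ratio(cy), 2 / 0.003 + 2 / 0.006)  # 1000 1/m
  expect_equal(projected_area(cy), pi * 0.003^2)
})

test_that("validation colony A/V ratios come out in 1/m", {
  expect_equal(av_ratio(coral_shape("hemisphere", 0.0175)), 257.1, tolerance = 1e-3)
  expect_equal(av_ratio(coral_shape("hemisphere", 0.025)), 180)
})

test_that("degenerate and invalid shapes are rejected", {
  expect_error(coral_shape("hemisphere", 0), "radius")
  expect_error(coral_shape("cylinder", 0.003), "height")
  expect_error(coral_shape("hemisphere", 0.01, tissue_thickness = 0.02),
               "tissue_thickness")
  # area and volume shrink to zero with the radius
  rs <- 10^seq(-3, -6)
  As <- vapply(rs, function(r) surface_area(coral_shape("hemisphere", r,
    tissue_thickness = r / 10)), 1)
  expect_true(all(diff(As) < 0) && As[length(As)] < 1e-11)
})

test_that("mesh zones partition the chamber and approximate coral volume", {
  dom <- chamber_domain()
  h <- coral_shape("hemisphere", 0.0175)
  m <- build_mesh(dom, h, c(48, 26, 26))
  zs <- zone_summary(m)
  expect_equal(sum(zs$cells), prod(dim(m$zone)))
  expect_equal(sum(zs$volume), dom$length * dom$width * dom$height,
               tolerance = 1e-10)
  # tagged coral volume within 5% of (2/3) pi r^3
  expect_equal(sum(zs$volume[zs$zone != "fluid"]), volume(h),
               tolerance = 0.05)
  expect_gt(zs$cells[zs$zone == "tissue"], 0)
})

test_that("zone volumes converge towards the analytic volume on refinement", {
  dom <- chamber_domain()
  h <- coral_shape("hemisphere", 0.0175)
  errs <- vapply(list(c(32, 18, 18), c(48, 26, 26), c(72, 40, 40)),
    function(res) {
      zs <- zone_summary(build_mesh(dom, h, res))
      abs(sum(zs$volume[zs$zone != "fluid"]) - volume(h)) / volume(h)
    }, 1)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("cylinder zone occupies the prescribed footprint and height", {
  dom <- chamber_domain()
  cy <- coral_shape("cylinder", radius = 0.003, height = 0.006)
  m <- build_mesh(dom, cy, c(52, 28, 30))
  coral <- m$zone != 0L
  ks <- which(apply(coral, 3, any))
  expect_lt(max(m$z[ks]), 0.006)           # no coral above branch height
  ij <- which(apply(coral, c(1, 2), any), arr.ind = TRUE)
  rad <- sqrt((m$x[ij[, 1]] - m$centre[1])^2 + (m$y[ij[, 2]] - m$centre[2])^2)
  expect_lt(max(rad), 0.003)               # footprint inside the radius
})

test_that("meshes that cannot resolve the coral are rejected", {
  dom <- chamber_domain()
  h <- coral_shape("hemisphere", 0.0175)
  expect_error(build_mesh(dom, h, c(10, 6, 6)), "coarse")
  big <- coral_shape("hemisphere", 0.06)
  expect_error(build_mesh(dom, big, c(48, 26, 26)), "fit")
})

test_that("grading refines near the coral relative to the far field", {
  m <- build_mesh(chamber_domain(), coral_shape("hemisphere", 0.0175),
                  c(48, 26, 26))
  expect_gte(max(m$dx) / min(m$dx), 2)
  # expansion ratio between adjacent cells stays near the requested 1.2
  expect_lt(max(m$dx[-1] / m$dx[-length(m$dx)]), 1.35)
})

test_that("boundary patch areas close the domain surface", {
  dom <- chamber_domain()
  m <- build_mesh(dom, NULL, c(12, 6, 8))
  case <- fvm_case(m, bcs = boundary_set(bottom_mode = "slip"))
  A_patches <- 2 * sum(case$geom$Ax_b) + 2 * sum(case$geom$Ay_b) +
    2 * sum(case$geom$Az_b)
  A_outer <- 2 * (dom$width * dom$height + dom$length * dom$height +
                    dom$length * dom$width)
  expect_equal(A_patches, A_outer, tolerance = 1e-12)
})
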