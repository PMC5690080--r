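geom_th <- beam_geometry(100, 200, 1.2)

test_that("polarity averaging cancels antisymmetric offsets exactly", {
  expect_equal(average_polarity(10.02, 9.98), 10)
  set.seed(31)
  R <- runif(200, 0.1, 10)
  delta <- runif(200, -0.05, 0.05) * R
  expect_equal(average_polarity(R + delta, R - delta), R, tolerance = 1e-14)
  # simulator cable offset at 0.5% of the reading cancels the same way
  model <- synthetic_beam_model(cable_offset_fraction = 0.005)
  scan <- simulate_moving_gantry_scan(model, geom_th, c(0, 5, 10))
  clean <- synthetic_beam_model()
  ref <- simulate_moving_gantry_scan(clean, geom_th, c(0, 5, 10))
  expect_equal(average_polarity(scan$reading_plus, scan$reading_minus),
               ref$reading_plus, tolerance = 1e-14)
  expect_error(average_polarity(0, 0), "positive")
})

test_that("beam_profile enforces ordered coordinates", {
  expect_error(beam_profile(c(0, 2, 1), c(1, 1, 1)), "strictly increasing")
  expect_error(beam_profile(c(-1, 0, 1), c(1, 1, 1)), "unsigned")
  p <- beam_profile(c(0, 10, 20), c(1, 0.9, 0.5), geom = geom_th)
  expect_s3_class(as.data.frame(p), "data.frame")
})

test_that("transforming a gantry scan preserves points and lands on increasing x", {
  model <- synthetic_beam_model()
  betas <- seq(0, 20, by = 1)
  scan <- simulate_moving_gantry_scan(model, geom_th, betas)
  prof <- transform_gantry_profile(scan, geom_th, response_preset("thimble-300"))
  expect_equal(nrow(prof$data), length(betas))
  expect_true(all(diff(prof$data$x) > 0))
  expect_identical(prof$setup, "moving_detector")
  # the single on-axis point passes through unchanged
  one <- data.frame(beta = 0, reading_plus = 1.5, reading_minus = 1.5)
  p1 <- transform_gantry_profile(one, geom_th, response_preset("thimble-300"))
  expect_identical(p1$data$x, 0)
  expect_identical(p1$data$value, 1.5)
})

test_that("normalization scales the reference to 100% and is idempotent", {
  p <- beam_profile(c(0, 10, 20), c(7, 7, 7))
  n1 <- normalize_profile(p)
  expect_identical(n1$data$value, c(100, 100, 100))
  expect_identical(normalize_profile(n1)$data$value, n1$data$value)
  pm <- beam_profile(c(1, 10, 20), c(2, 8, 4))
  expect_equal(normalize_profile(pm, "maximum")$data$value, c(25, 100, 50))
  expect_error(normalize_profile(pm, "central_axis"), "x = 0")
})

test_that("interpolation is exact on the grid, linear between, no extrapolation", {
  p <- beam_profile(c(0, 10, 20), c(100, 80, 20), normalized = TRUE)
  expect_identical(interpolate_profile(p, c(0, 10, 20)), c(100, 80, 20))
  expect_equal(interpolate_profile(p, 15), 50)
  expect_error(interpolate_profile(p, 25), "outside")
  # dense erf-penumbra profile interpolates to the analytic value
  model <- synthetic_beam_model()
  xs <- seq(0, 90, by = 0.5)
  scan <- simulate_moving_detector_scan(model, geom_th, xs)
  prof <- normalize_profile(beam_profile(xs, scan$reading_plus, geom = geom_th))
  x0 <- 55.25
  a0 <- atan(x0 / geom_th$scd) * 180 / pi
  truth <- fluence_at_angle(model, a0) * cos(a0 * pi / 180)^2 *
    directional_response(model$response_model, a0) /
    scan$reading_plus[1] * 100
  expect_equal(interpolate_profile(prof, x0), truth, tolerance = 5e-4)
})

test_that("the 50% point is located by linear interpolation and is scale invariant", {
  ramp <- beam_profile(c(60, 80), c(100, 0), normalized = TRUE)
  expect_equal(half_value_position(ramp), 70)
  flat <- beam_profile(c(0, 10, 20), c(100, 100, 100), normalized = TRUE)
  expect_error(half_value_position(flat), "never descends")
  wavy <- beam_profile(c(0, 1, 2, 3), c(100, 40, 60, 30), normalized = TRUE)
  expect_error(half_value_position(wavy), "more than once")
  # invariant under uniform rescaling before normalization
  xs <- seq(0, 90, by = 1)
  model <- synthetic_beam_model()
  v <- simulate_moving_detector_scan(model, geom_th, xs)$reading_plus
  h1 <- half_value_position(normalize_profile(beam_profile(xs, v)))
  h2 <- half_value_position(normalize_profile(beam_profile(xs, 3.7 * v)))
  expect_identical(h1, h2)
  # the erf edge puts the 50% level near the field-edge ray
  x_edge <- geom_th$scd * tan(model$theta_edge * pi / 180)
  expect_lt(abs(h1 - x_edge), 1.5)
})

test_that("profile comparison reports pointwise differences in percent of CAX", {
  p <- beam_profile(c(0, 10, 20, 30), c(100, 90, 50, 10), normalized = TRUE)
  same <- compare_profiles(p, p)
  expect_identical(same$table$diff, rep(0, 4))
  expect_identical(same$max_abs_diff, 0)
  p2 <- beam_profile(c(0, 10, 20, 30), c(100, 90, 50, 10) * 1.01,
                     normalized = TRUE)
  cmp <- compare_profiles(p2, p)
  expect_equal(cmp$table$diff, 0.01 * c(100, 90, 50, 10))
  disjoint <- beam_profile(c(40, 50), c(5, 1), normalized = TRUE)
  expect_error(compare_profiles(p, disjoint), "overlap")
  expect_error(compare_profiles(p, beam_profile(c(0, 10), c(1, 2))),
               "normalized")
})

test_that("distances project between planes by similar triangles", {
  expect_equal(round(project_distance(0.95, 300, 100), 2), 0.32)
  expect_identical(project_distance(12.5, 300, 300), 12.5)
  expect_equal(project_distance(18, 100, 300), 54)   # half-side 36 -> 108 field
  expect_error(project_distance(1, 0, 100), "positive")
})
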