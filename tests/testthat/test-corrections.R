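geom_th <- beam_geometry(100, 200, 1.2)
geom_mk <- beam_geometry(100, 200, 0.2)

test_that("directional response is exactly 1 at perpendicular incidence and monotone", {
  for (name in c("thimble-300", "markus-100", "markus-300")) {
    m <- response_preset(name)
    expect_identical(directional_response(m, 0), 1)
    r <- directional_response(m, seq(0, 20, 0.5))
    if (m$form == "diminishing") expect_true(all(diff(r) < 0))
    else expect_true(all(diff(r) > 0))
  }
})

test_that("preset evaluations match independent arithmetic", {
  th <- response_preset("thimble-300")
  expect_equal(directional_response(th, 13.39), 1 - 0.00018 * 13.39^2)
  expect_equal(round(directional_response(th, 13.39), 5), 0.96773)
  mk3 <- response_preset("markus-300")
  phi <- incidence_angle(20, geom_mk)
  # the enhancing factor at the 20-degree scan edge is ~1.0025-1.0026
  expect_equal(directional_response(mk3, phi), 1 + 0.0000325 * phi^2.3)
  expect_equal(directional_response(mk3, phi), 1.0026, tolerance = 2e-4)
  mk1 <- response_preset("markus-100")
  expect_equal(catt_obl_markus(mk1, 10), 1 / (1 + 0.0000114 * 10^2.5))
  expect_equal(round(catt_obl_markus(mk1, 10), 4), 0.9964)
})

test_that("evaluation beyond the calibrated sweep warns but still returns", {
  th <- response_preset("thimble-300")   # calibrated to 20 degrees
  expect_warning(r <- directional_response(th, 25), "extrapolated")
  expect_equal(r, 1 - 0.00018 * 25^2)
  expect_error(directional_response(th, -1), "nonnegative")
})

test_that("thimble attenuation correction is the response ratio at alpha and phi", {
  th <- response_preset("thimble-300")
  expect_identical(catt_thimble(th, 10, 10), 1)
  got <- catt_thimble(th, 13.39, 6.61)
  expect_equal(got, (1 - 0.00018 * 13.39^2) / (1 - 0.00018 * 6.61^2))
  expect_equal(round(got, 4), 0.9754)
  expect_equal(catt_thimble(th, 13.39, 0), 1 - 0.00018 * 13.39^2)
  # the classical ray always traverses more phantom material
  set.seed(7)
  a <- runif(50, 0, 20); p <- a * runif(50, 0, 0.99)
  expect_true(all(catt_thimble(th, a, p) < 1))
  expect_error(catt_thimble(response_preset("markus-300"), 5, 3), "diminishing")
})

test_that("Markus correction is the reciprocal enhancing response, applied per setup", {
  mk <- response_preset("markus-300")
  expect_identical(catt_obl_markus(mk, 0), 1)
  expect_true(all(catt_obl_markus(mk, seq(0, 30, 1)) <= 1))
  expect_equal(catt_obl_markus(mk, 6.6), 1 / (1 + 0.0000325 * 6.6^2.3))
  expect_error(catt_obl_markus(response_preset("thimble-300"), 5), "enhancing")
  # in the moving-gantry setup the Markus directional factor is negligible
  phi <- incidence_angle(20, geom_mk)
  expect_lt(abs(1 - catt_obl_markus(mk, phi)), 0.003)
})

test_that("noise-free fits recover the generating power law exactly", {
  phi <- c(0, 5, 10, 15, 20)
  fit <- fit_directional_response(phi, 1 - 0.00018 * phi^2.0, "diminishing")
  expect_equal(fit$a, 0.00018, tolerance = 1e-6)
  expect_equal(fit$b, 2.0, tolerance = 1e-6)

  phi <- c(0, 5, 10, 15, 20, 25, 30)
  fit <- fit_directional_response(phi, 1 + 0.0000325 * phi^2.3, "enhancing")
  expect_equal(fit$a, 0.0000325, tolerance = 1e-6)
  expect_equal(fit$b, 2.3, tolerance = 1e-6)
  expect_lt(fit$fit$residual_norm, 1e-12)
})

test_that("fit recovery holds across the (a, b) parameter box", {
  set.seed(99)
  phi <- seq(0, 30, length.out = 11)
  for (i in 1:20) {
    a <- 10^runif(1, -6, -3)
    b <- runif(1, 1.5, 3)
    for (form in c("diminishing", "enhancing")) {
      sgn <- if (form == "diminishing") -1 else 1
      # a diminishing law must stay well above zero over the sweep
      if (form == "diminishing" && a * max(phi)^b >= 0.9) next
      fit <- fit_directional_response(phi, 1 + sgn * a * phi^b, form)
      expect_equal(fit$a, a, tolerance = 1e-6)
      expect_equal(fit$b, b, tolerance = 1e-6)
    }
  }
})

test_that("fits under measurement noise recover the truth within 10%", {
  set.seed(2024)
  phi <- seq(0, 30, length.out = 30)
  truth_a <- 0.0000325; truth_b <- 2.3
  rel <- 1 + truth_a * phi^truth_b + rnorm(30, sd = 0.001)
  fit <- fit_directional_response(phi, rel, "enhancing")
  expect_lt(abs(fit$a * 30^fit$b - truth_a * 30^truth_b) /
              (truth_a * 30^truth_b), 0.10)
  # the response curve itself is recovered within 10% of its deviation
  # from unity over the calibrated range
  dev_true <- truth_a * phi[-1]^truth_b
  dev_fit <- fit$a * phi[-1]^fit$b
  expect_lt(max(abs(dev_fit - dev_true) / pmax(dev_true, 1e-6)), 0.10)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_directional_response(c(0, 10), c(1, 0.99), "diminishing"),
               "at least 3")
  expect_error(fit_directional_response(c(0, 5, 10), c(1, -0.1, 0.9),
                                        "diminishing"), "positive")
  expect_warning(fit_directional_response(c(5, 10, 15, 20),
                                          1 - 0.00018 * c(5, 10, 15, 20)^2,
                                          "diminishing"), "perpendicular")
})

test_that("the correction chain multiplies out as Cisq * Catt * Cobl", {
  th <- response_preset("thimble-300")
  # on axis every factor is 1 and the reading is untouched
  res0 <- correct_reading(2.5, 0, geom_th, th)
  expect_identical(res0$corrected, 2.5)
  expect_identical(res0$breakdown$combined, 1)

  # worked point at the scan edge: product of the two factor oracles
  o <- oracle_ray(20, 100, 200, 1.2)
  catt <- (1 - 0.00018 * o$alpha^2) / (1 - 0.00018 * o$phi^2)
  res <- correct_reading(1.000, 20, geom_th, th)
  expect_equal(res$corrected, o$c_isq * catt, tolerance = 1e-12)
  expect_equal(round(res$corrected, 4), 0.8984)
  expect_equal(res$breakdown$combined,
               res$breakdown$c_isq * res$breakdown$c_att * res$breakdown$c_obl)
  expect_true(all(res$breakdown[c("c_isq", "c_att", "c_obl")] > 0))

  # linear in the reading
  expect_equal(correct_reading(7 * 1.3, 12, geom_th, th)$corrected,
               7 * correct_reading(1.3, 12, geom_th, th)$corrected)
})

test_that("correction mode and model form must match", {
  expect_error(correct_reading(1, 10, geom_th, response_preset("markus-300"),
                               "thimble_ratio"), "diminishing")
  expect_error(correct_reading(1, 10, geom_mk, response_preset("thimble-300"),
                               "markus_per_setup"), "enhancing")
  expect_error(correct_reading(-1, 10, geom_th, response_preset("thimble-300")),
               "positive")
})
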