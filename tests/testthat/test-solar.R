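test_that("solar declination hits the equinox and solstice anchors", {
  expect_lt(abs(solar_declination(80)), 0.01) # vernal equinox
  expect_equal(solar_declination(172), 23.45 * pi / 180, tolerance = 1e-2)
  expect_equal(solar_declination(355), -23.45 * pi / 180, tolerance = 1e-2)
  expect_true(all(abs(solar_declination(1:365)) <= 23.45 * pi / 180 + 1e-12))
  expect_error(solar_declination(0), "day_of_year")
  expect_error(solar_declination(366), "day_of_year")
})

test_that("surface irradiance follows the clearness-scaled solar cycle", {
  # opaque sky kills all light
  hours <- seq(0, 23.5, by = 0.5)
  expect_true(all(surface_irradiance(40, 172, hours, 0) == 0))

  # noon value matches direct substitution into the solar-cycle expression
  sc <- 2500
  delta <- solar_declination(80)
  phi <- 40 * pi / 180
  expected <- sc * (sin(phi) * sin(delta) - cos(phi) * cos(delta) * cos(pi)) * 0.7
  expect_equal(surface_irradiance(40, 80, 12, 0.7, sc), expected,
               tolerance = 1e-12)
  # with the equinox declination ~0 this is ~ SC cos(lat) Lambda
  expect_equal(expected / sc, cos(phi) * 0.7, tolerance = 1e-2)

  # negative solar elevation is clamped to zero (night)
  expect_identical(surface_irradiance(40, 355, 0, 0.7), 0)
  expect_gt(surface_irradiance(40, 172, 12, 0.7), 0)

  # daily light dose is monotone in the clearness index
  dose <- vapply(c(0.2, 0.5, 0.8),
                 function(l) sum(surface_irradiance(40, 100, hours, l)),
                 numeric(1))
  expect_true(all(diff(dose) > 0))
})

test_that("shading angle has the geometric limits", {
  expect_equal(shading_angle(0, 0.15), pi)
  expect_equal(shading_angle(0.075, 0.15), pi / 2) # z = s/2
  expect_equal(shading_angle(0.28, 0.15), 0.5235, tolerance = 1e-3)
  z <- seq(0, 1, by = 0.01)
  expect_true(all(diff(shading_angle(z, 0.15)) < 0))
  expect_error(shading_angle(-1, 0.15), ">= 0")
})

test_that("panel irradiance at height scales the visible-sky fraction", {
  expect_identical(panel_irradiance_at_height(0, 0.1, 0.15), 0)
  expect_equal(panel_irradiance_at_height(1000, 0, 0.15), 1000)
  expect_equal(panel_irradiance_at_height(1000, 0.28, 0.15), 166.6,
               tolerance = 1e-3)
})

test_that("closed-form panel average equals quadrature of the shading profile", {
  hs <- expand.grid(h = seq(0.05, 2, length.out = 20),
                    s = seq(0.02, 1, length.out = 20))
  for (i in seq_len(nrow(hs))) {
    h <- hs$h[i]; s <- hs$s[i]
    closed <- panel_shading_ratio(h, s)
    quad <- integrate(function(z) shading_angle(z, s) / pi, 0, h,
                      rel.tol = 1e-10)$value / h
    expect_equal(closed, quad, tolerance = 1e-6)
  }
})

test_that("panel average has the analytic limits and scale invariance", {
  expect_equal(panel_shading_ratio(0.28, 1e5), 1, tolerance = 1e-4)
  expect_lt(panel_shading_ratio(0.28, 1e-7), 1e-4)
  # depends only on s/h
  expect_equal(panel_shading_ratio(0.28, 0.15), panel_shading_ratio(2.8, 1.5),
               tolerance = 1e-12)
  # monotone: more separation -> brighter; taller panel -> dimmer
  s <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(vapply(s, panel_shading_ratio, numeric(1),
                              height_m = 0.28)) > 0))
  h <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(vapply(h, panel_shading_ratio, numeric(1),
                              separation_m = 0.15)) < 0))
  # the reference geometry ratio
  expect_equal(panel_shading_ratio(0.28, 0.15), 0.3972, tolerance = 2e-4)
  expect_equal(average_panel_irradiance(1000, panel_geometry()), 397.2,
               tolerance = 0.1)
})

test_that("irradiance calendar is consistent with the point model", {
  site <- list(latitude_deg = 40, clearness = rep(0.7, 12))
  cal <- irradiance_calendar(site, panel_geometry(), days = 3)
  expect_equal(nrow(cal), 3 * 128)
  expect_true(all(cal$e_avg_panel <= cal$e0 + 1e-12))
  expect_true(all(cal$e0 >= 0))
  i <- 200
  expect_equal(cal$e0[i],
               surface_irradiance(40, cal$day_of_year[i], cal$hour[i], 0.7))
  expect_error(irradiance_calendar(site, panel_geometry(), dt_min = 7),
               "divide")
})
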