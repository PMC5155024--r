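test_that("normalised quota curve has the right anchors and shape", {
  expect_equal(quota_limitation(0.05, 0.05, 0.20, 0.25), 0)
  expect_equal(quota_limitation(0.20, 0.05, 0.20, 0.25), 1)
  expect_equal(quota_limitation(0.125, 0.05, 0.20, 1), 2 / 3, tolerance = 1e-12)
  q <- seq(0.05, 0.20, length.out = 50)
  expect_true(all(diff(quota_limitation(q, 0.05, 0.20, 0.25)) > 0))
  expect_warning(quota_limitation(0.3, 0.05, 0.2, 0.25), "clamping")
})

test_that("uptake saturates in substrate and shuts down at full quota", {
  expect_equal(nutrient_uptake(0, 0.3, 0.14, 0.1, 0.05, 0.2), 0)
  expect_equal(nutrient_uptake(5, 0.3, 0.14, 0.2, 0.05, 0.2), 0)
  expect_equal(nutrient_uptake(0.14, 0.3, 0.14, 0.05, 0.05, 0.2), 0.15)
})

test_that("ammonium is consumed before nitrate", {
  expect_equal(ammonium_preference(10, 0, 1),
               c(uptake_n = 1, uptake_a = 0))
  expect_equal(ammonium_preference(10, 50, 1),
               c(uptake_n = 0, uptake_a = 1))
  expect_equal(ammonium_preference(10, 0.3, 1),
               c(uptake_n = 0.7, uptake_a = 0.3))
  expect_equal(sum(ammonium_preference(0.2, 0.3, 1)), 0.5) # capped by supply
})

test_that("growth follows the threshold (Liebig) law across variants", {
  p <- physiology_params(mu_winter = 1, mu_summer = 1.5)
  s <- algal_state(nc = 0.11, pc = 0.012)
  f_n <- quota_limitation(0.11, p$ncmin, p$ncmax, p$kq_n)
  f_p <- quota_limitation(0.012, p$pcmin, p$pcmax, p$kq_p)
  expect_equal(growth_rate(s, p, ps_net = 1.2, mu_m = 1.5),
               min(1.2, 1.5 * f_n, 1.5 * f_p))
  # N-starved cells do not grow even in bright light
  s0 <- algal_state(nc = p$ncmin)
  expect_lte(growth_rate(s0, p, ps_net = 1.2, mu_m = 1.5), 0)
  # replete, light-saturated growth runs at mu_m
  sr <- algal_state(nc = p$ncmax, pc = p$pcmax)
  expect_equal(growth_rate(sr, p, ps_net = 99, mu_m = 1.5), 1.5)
  # CN and CNCHL drop the P limitation
  p_cn <- physiology_params(variant = "CN")
  s_plow <- algal_state(nc = 0.2, pc = 0.0051)
  expect_equal(growth_rate(s_plow, p_cn, ps_net = 99, mu_m = 1.5), 1.5)
})

test_that("Chl:C rises under light limitation and falls under saturation", {
  p <- physiology_params()
  s <- algal_state(nc = p$ncmax, chlc = 0.02)
  up <- chl_dynamics(s, p, ps_achieved = 0.05, ps_lightsat = 2, dt = 0.5)
  expect_gt(up, s$chlc) # deep light limitation, N replete -> more pigment
  down <- chl_dynamics(s, p, ps_achieved = 2, ps_lightsat = 2, dt = 0.5)
  expect_lt(down, s$chlc) # saturating light sheds pigment
  # relaxation target is capped at the attainable ceiling
  many <- Reduce(function(ch, i) {
    chl_dynamics(algal_state(nc = p$ncmax, chlc = ch), p, 0, 2, 0.5)
  }, 1:40, accumulate = FALSE, init = 0.02)
  expect_equal(many, p$chlc_m, tolerance = 1e-6)
  # constant-pigment variants never move
  p_cn <- physiology_params(variant = "CN")
  expect_identical(chl_dynamics(s, p_cn, 0, 2, 1), s$chlc)
})

test_that("storage fraction interpolates between its endpoints", {
  p <- physiology_params()
  expect_equal(storage_fraction(p$ncmax, p), p$cexc_base)
  expect_equal(storage_fraction(p$ncmin, p), p$cexc_max)
  mid <- (p$ncmin + p$ncmax) / 2
  expect_equal(storage_fraction(mid, p), (p$cexc_base + p$cexc_max) / 2)
  nc <- seq(p$ncmin, p$ncmax, length.out = 20)
  expect_true(all(diff(storage_fraction(nc, p)) < 0))
  p_f <- physiology_params(variant = "FIXED")
  expect_equal(storage_fraction(0.08, p_f), p_f$cexc_fixed)
})

test_that("a replete light-saturated Euler step tracks exponential growth", {
  p <- physiology_params(force_replete = TRUE)
  optics <- list(k_background = 0.1, k_chl = 0.012, tau_m = 0.025)
  dt <- 11.25 / 1440
  s <- algal_state(tc = 100, nc = p$ncmax, pc = p$pcmax, chlc = 0.02)
  out <- step_physiology(s, p, list(e_avg_panel = 1e6), optics, dt, mu_m = 1.5)
  euler_factor <- out$tc / s$tc
  expect_equal(euler_factor, 1 + 1.5 * dt, tolerance = 1e-6) # 1.01172
  expect_equal(exp(1.5 * dt), 1.01179, tolerance = 1e-5)
  expect_lt(abs(euler_factor - exp(1.5 * dt)), 1e-4)
})

test_that("dark steps respire carbon and nothing else grows", {
  p <- physiology_params()
  optics <- list(k_background = 0.1, k_chl = 0.012, tau_m = 0.025)
  s <- algal_state()
  out <- step_physiology(s, p, list(e_avg_panel = 0), optics, dt = 0.01)
  d <- attr(out, "diag")
  expect_equal(d$ps, 0)
  expect_equal(d$mu, -p$r_basal) # only basal respiration in the dark
  expect_lt(out$tc, s$tc)
})

test_that("single steps conserve N and P between pools", {
  p <- physiology_params()
  optics <- list(k_background = 0.1, k_chl = 0.012, tau_m = 0.025)
  set.seed(7)
  for (i in 1:25) {
    s <- algal_state(tc = runif(1, 20, 900), nc = runif(1, 0.05, 0.2),
                     pc = runif(1, 0.005, 0.03), chlc = runif(1, 0.002, 0.033),
                     din_n = runif(1, 0, 60), din_a = runif(1, 0, 5),
                     dip = runif(1, 0, 5))
    out <- step_physiology(s, p, list(e_avg_panel = runif(1, 0, 800)),
                           optics, dt = 11.25 / 1440,
                           mu_m = runif(1, 1.04, 1.5))
    n0 <- s$din_n + s$din_a + s$nc * s$tc
    n1 <- out$din_n + out$din_a + out$nc * out$tc
    expect_equal(n1, n0, tolerance = 1e-9)
    p0 <- s$dip + s$pc * s$tc
    p1 <- out$dip + out$pc * out$tc
    expect_equal(p1, p0, tolerance = 1e-9)
  }
})

test_that("quota bounds hold after every step", {
  p <- physiology_params()
  optics <- list(k_background = 0.1, k_chl = 0.012, tau_m = 0.025)
  set.seed(8)
  for (i in 1:20) {
    s <- algal_state(tc = runif(1, 10, 600), nc = runif(1, 0.05, 0.2),
                     pc = runif(1, 0.005, 0.03),
                     din_n = runif(1, 0, 61.6), dip = runif(1, 0, 5.5))
    out <- step_physiology(s, p, list(e_avg_panel = runif(1, 0, 600)),
                           optics, dt = 0.05)
    expect_gte(out$nc, p$ncmin - 1e-12)
    expect_lte(out$nc, p$ncmax + 1e-12)
    expect_gte(out$pc, p$pcmin - 1e-12)
    expect_lte(out$pc, p$pcmax + 1e-12)
    expect_gte(out$chlc, p$chlc_min - 1e-12)
    expect_lte(out$chlc, p$chlc_m + 1e-12)
  }
})

test_that("the fast stepper reproduces the reference step exactly", {
  optics <- list(k_background = 0.1, k_chl = 0.012, tau_m = 0.025)
  dt <- 11.25 / 1440
  set.seed(9)
  for (variant in c("CNPCHL", "CNCHL", "CN", "FIXED")) {
    p <- physiology_params(variant = variant)
    stepper <- pbrsim:::make_stepper(p, optics)
    for (i in 1:15) {
      nc0 <- if (variant == "FIXED") p$nc_fixed else runif(1, 0.05, 0.2)
      pc0 <- if (variant == "FIXED") p$pc_fixed else runif(1, 0.005, 0.03)
      s <- algal_state(tc = runif(1, 15, 900), nc = nc0, pc = pc0,
                       chlc = runif(1, 0.002, 0.033),
                       din_n = runif(1, 0, 61.6), din_a = runif(1, 0, 3),
                       dip = runif(1, 0, 5.5))
      e <- runif(1, 0, 900)
      mu_m <- runif(1, 1.04, 1.5)
      ref <- step_physiology(s, p, list(e_avg_panel = e), optics, dt, mu_m)
      d <- attr(ref, "diag")
      sv <- stepper(c(s$tc, s$nc, s$pc, s$chlc, s$din_n, s$din_a, s$dip,
                      s$dic, s$cexc), e, mu_m, dt)
      expect_equal(sv[1:8],
                   c(ref$tc, ref$nc, ref$pc, ref$chlc, ref$din_n, ref$din_a,
                     ref$dip, ref$dic), tolerance = 1e-14)
      expect_equal(sv[9:15],
                   c(ref$cexc, d$ps, d$resp, d$mu, d$k, d$fixed_c, d$resp_c),
                   tolerance = 1e-14)
    }
  }
})

test_that("the FIXED variant holds Redfield stoichiometry exactly", {
  cfg <- pbr_config(strain = list(variant = "FIXED"),
                    operation = list(sim_days = 5))
  cfg$initial$nc <- 0.176
  cfg$initial$pc <- 0.024
  sim <- run_simulation(cfg)
  expect_true(all(sim$trajectory$nc == 0.176))
  expect_true(all(sim$trajectory$pc == 0.024))
})
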