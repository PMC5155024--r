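test_that("seasonal mu_m interpolates between the winter and summer endpoints", {
  expect_equal(seasonal_mu_max(15), 1.04)
  expect_equal(seasonal_mu_max(15 + 182), 1.5, tolerance = 1e-4)
  expect_equal(seasonal_mu_max(15 + 91), 1.27, tolerance = 1e-2) # quarter year
  expect_error(seasonal_mu_max(400), "day_of_year")
})

test_that("harvest events move mass to the ledger and refresh the medium", {
  plan <- list(dil = 0.3, nut_n = 61.6, nut_p = 5.5)
  s <- algal_state(tc = 600, cexc = 0.35, nc = 0.1, din_n = 5)
  out <- harvest_event(s, plan, volume = 0.242)
  expect_equal(out$hc, 43.56, tolerance = 1e-10)
  expect_equal(out$hexc, 15.246, tolerance = 1e-10)
  expect_equal(out$tc, 0.7 * 600)
  # intensive quotas are untouched; dissolved pools relax to the medium
  expect_equal(out$nc, s$nc)
  expect_equal(out$cexc, s$cexc)
  expect_equal(out$din_n, 0.7 * 5 + 0.3 * 61.6)

  # no-op and washout-guard extremes
  expect_equal(harvest_event(s, list(dil = 0, nut_n = 0, nut_p = 0), 1)$tc,
               s$tc)
  drained <- harvest_event(s, list(dil = 1, nut_n = 61.6, nut_p = 5.5,
                                   inoculum_floor = 10), 1)
  expect_equal(drained$tc, 10) # never below the inoculum floor
  expect_equal(drained$hc, 590)
  expect_error(harvest_event(s, list(dil = 1.5), 1), "dil")
})

test_that("degenerate runs behave: empty span and permanent darkness", {
  sim0 <- run_simulation(fast_config(0))
  expect_equal(nrow(sim0$trajectory), 1)
  expect_equal(nrow(sim0$ledger), 0)

  dark <- pbr_config(site = list(clearness = rep(0, 12)),
                     operation = list(sim_days = 8, dil = 0))
  sim <- run_simulation(dark)
  expect_true(all(diff(sim$trajectory$tc) < 0)) # respiration-only decline
  expect_true(all(sim$trajectory$mu[-1] <= 0))
  expect_equal(volumetric_production(sim), 0)
})

test_that("element ledgers close over multi-week runs with harvesting", {
  for (variant in c("CNPCHL", "CNCHL")) {
    sim <- run_simulation(pbr_config(strain = list(variant = variant),
                                     operation = list(sim_days = 30,
                                                      harvest_interval_d = 4)))
    res <- ledger_residuals(sim)
    expect_lt(max(abs(res)), 1e-9)
  }
})

test_that("all variants collapse to one light-limited model when replete", {
  runs <- lapply(c("CNPCHL", "CNCHL", "CN", "FIXED"), function(v) {
    cfg <- pbr_config(
      strain = list(variant = v, force_replete = TRUE, rho_chl = 0,
                    chlc_fixed = 0.02),
      operation = list(sim_days = 5),
      initial = list(chlc = 0.02)
    )
    run_simulation(cfg)$trajectory$tc
  })
  for (i in 2:4) expect_equal(runs[[i]], runs[[1]], tolerance = 1e-12)
})

test_that("chemostat steady state grows at the imposed dilution rate", {
  rate <- 0.3
  sim <- run_simulation(chemostat_config(days = 40, rate = rate))
  tr <- sim$trajectory
  late <- tr$time_d > 30
  mean_mu <- mean(tr$mu[late], na.rm = TRUE)
  expect_equal(mean_mu, rate, tolerance = 0.01)
  # biomass has stopped trending
  tc_late <- tr$tc[late]
  expect_lt(abs(tc_late[length(tc_late)] / tc_late[1] - 1), 0.02)
})

test_that("production accounting matches the harvest ledger arithmetic", {
  sim <- run_simulation(fast_config(10))
  led <- sim$ledger
  expect_equal(nrow(led), 10) # daily harvest, terminal event included
  expect_equal(volumetric_production(sim),
               sum(led$harvested_c_g) / (sim$volume_m3 * 10))
  expect_equal(areal_feedstock_production(sim),
               sum(led$harvested_storage_g) / (sim$footprint_m2 * 10))
  # a one-day window holds a single harvest
  w <- volumetric_production(sim, c(4, 5))
  one <- led$harvested_c_g[led$time_d == 5]
  expect_equal(w, one / sim$volume_m3)
  expect_error(volumetric_production(sim, c(5, 4)), "window")
  expect_error(volumetric_production(sim, c(0, 99)), "span")
  # ledger totals equal the cumulative harvested pools of the final state
  expect_equal(sum(led$harvested_c_g), sim$accounting$final$hc)
  expect_equal(sum(led$harvested_storage_g), sim$accounting$final$hexc)
  # volume-to-footprint factor of the reference geometry
  expect_equal(sim$volume_m3 / sim$footprint_m2, 0.07, tolerance = 1e-12)
})

test_that("daily series sums to standing change plus harvests", {
  sim <- run_simulation(fast_config(12, harvest_interval_d = 4))
  dp <- daily_production(sim)
  expect_equal(nrow(dp), 12)
  tr <- sim$trajectory
  in_days <- sim$ledger$time_d < 12
  total <- (tr$tc[nrow(tr)] - tr$tc[1]) +
    sum(sim$ledger$harvested_c_g[in_days]) / sim$volume_m3
  expect_equal(sum(dp$vp), total, tolerance = 1e-9)
})

test_that("monthly summary aggregates by calendar month", {
  sim <- run_simulation(fast_config(59)) # spans January and February
  ms <- monthly_summary(sim)
  expect_equal(ms$month, c(1L, 2L))
  expect_equal(ms$n_days, c(31L, 28L))
  dp <- daily_production(sim)
  expect_equal(ms$mean_vp[1], mean(dp$vp[dp$month == 1]))
})

test_that("Euler and RK4 integrations agree at the production step size", {
  cfg <- fast_config(40)
  g_e <- glance(run_simulation(cfg, method = "euler"))
  g_r <- glance(run_simulation(cfg, method = "rk4"))
  expect_equal(g_e$mean_vp, g_r$mean_vp, tolerance = 0.02)
  expect_equal(g_e$mean_tc, g_r$mean_tc, tolerance = 0.02)
})

test_that("tidiers expose the run as tabular data", {
  sim <- run_simulation(fast_config(3))
  expect_s3_class(tidy(sim), "tbl_df")
  expect_equal(nrow(tidy(sim)), 3 * 128 + 1)
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_true(all(c("mean_vp", "peak_vp", "mean_axp", "peak_axp") %in%
                    names(g)))
  expect_s3_class(autoplot(sim), "ggplot")
})
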