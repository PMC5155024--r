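test_that("objective is a relative SSE with rejection of failed candidates", {
  pr <- calibration_problem(c(a = 0, b = 0), c(a = 2, b = 2),
                            function(p) c(y1 = p[["a"]], y2 = p[["b"]]),
                            c(y1 = 1, y2 = 0.5))
  expect_equal(objective(c(a = 1, b = 0.5), pr), 0)
  expect_gte(objective(c(a = 0.2, b = 1.9), pr), 0)
  expect_equal(objective(c(a = 2, b = 0.5), pr), 1) # one unit of rel. error
  expect_error(objective(c(a = 3, b = 0), pr), "bounds")
  pr_fail <- calibration_problem(c(a = 0), c(a = 1),
                                 function(p) stop("boom"), c(y = 1))
  expect_identical(objective(c(a = 0.5), pr_fail), Inf)
})

test_that("perturbing one month away from a consistent optimum raises the objective", {
  fx <- make_reference_fixtures(seed = 3)
  pr <- clearness_problem(fx$irradiance_targets)
  opt <- setNames(fx$lambda_true, paste0("clearness_", 1:12))
  o0 <- objective(opt, pr)
  expect_lt(o0, 1e-20)
  bump <- opt
  bump[5] <- if (bump[5] > 0.625) bump[5] - 0.1 else bump[5] + 0.1 # stay in bounds
  expect_gt(objective(bump, pr), o0)
})

test_that("adaptive random search is deterministic and monotone in its best", {
  pr <- calibration_problem(c(a = -1, b = -1), c(a = 1, b = 1),
                            function(p) c(y = (p[["a"]] - 0.3)^2 +
                                            (p[["b"]] + 0.4)^2 + 1),
                            c(y = 1))
  f1 <- random_search(pr, 150, seed = 5)
  f2 <- random_search(pr, 150, seed = 5)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace$best, f2$trace$best)
  expect_true(all(diff(f1$trace$best) <= 0))
  expect_equal(unname(f1$par), c(0.3, -0.4), tolerance = 0.02)
  f3 <- random_search(pr, 1, seed = 5)
  expect_equal(f3$n_eval, 1)
  expect_false(is.null(f3$par))
  # tidiers
  expect_equal(nrow(tidy(f1)), 2)
  expect_equal(glance(f1)$seed, 5)
  expect_s3_class(autoplot(f1), "ggplot")
})

test_that("the search does not disturb the global RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  pr <- calibration_problem(c(a = 0), c(a = 1),
                            function(p) c(y = p[["a"]]), c(y = 0.5))
  invisible(random_search(pr, 25, seed = 99))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("monthly clearness indices are recovered from irradiance targets", {
  fx <- make_reference_fixtures(seed = 11)
  pr <- clearness_problem(fx$irradiance_targets)
  fit <- random_search(pr, 2000, seed = 1)
  err <- abs(unname(fit$par) - fx$lambda_true)
  expect_lt(max(err), 0.02)
  expect_true(tuned_clearness_check(fit))
  expect_false(tuned_clearness_check(c(clearness_1 = 0.9)))
  expect_true(tuned_clearness_check(c(clearness_1 = 0.7)))
})

test_that("operating parameters are recovered from production targets", {
  # targets generated at known parameters from a short reference run
  true <- c(`operation.dil` = 0.10, `strain.alpha` = 0.45)
  base <- fast_config(10)
  gen <- base
  gen$operation$dil <- true[[1]]
  gen$strain$alpha <- true[[2]]
  g <- glance(run_simulation(gen))
  pr <- production_problem(base,
                           free = list(`operation.dil` = c(0.02, 0.3),
                                       `strain.alpha` = c(0.2, 0.8)),
                           targets = c(mean_vp = g$mean_vp,
                                       mean_axp = g$mean_axp,
                                       peak_vp = g$peak_vp))
  fit <- random_search(pr, 120, seed = 2)
  expect_lt(max(abs(fit$par / true - 1)), 0.05)
})
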