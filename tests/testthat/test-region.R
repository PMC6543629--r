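test_that("noise_profile pools the requested cycles across all wells", {
  plate <- simulate_plate(n_sets = 4, seed = 31)
  np <- noise_profile(plate, cycles = 1:10)
  expect_equal(np$n, 4 * 6 * 10)
  expect_equal(sum(np$histogram$count), np$n)
  expect_lte(np$min, np$max)
  expect_error(noise_profile(plate, cycles = integer(0)), "Empty")
  expect_error(noise_profile(plate, cycles = 30:40), "within")

  quiet <- simulate_plate(n_sets = 2, noise_sd = 0, seed = 1)
  np0 <- noise_profile(quiet, cycles = 1:5)
  expect_lt(np0$sd, 0.1)  # only sub-noise model signal remains
})

test_that("first outlier flags the takeoff cycle of a constructed series", {
  set.seed(71)
  rfu <- rnorm(33, 0, 0.5)
  rfu[16:33] <- 5 * 1.8^(0:17)  # noiseless takeoff after cycle 15
  expect_equal(first_outlier_cycle(rfu), 16L)

  # independent check via lm prediction intervals at the flagged cycle
  fit <- lm(y ~ x, data = data.frame(x = 1:15, y = rfu[1:15]))
  pr <- predict(fit, newdata = data.frame(x = 16), interval = "prediction",
                level = 1 - 2 * 0.01)  # one-sided 0.01
  expect_gt(rfu[16], pr[1, "upr"])
})

test_that("a strictly linear series yields no amplification call", {
  expect_identical(first_outlier_cycle(3 * (1:30) + 2), NA_integer_)
})

test_that("pure-noise series are almost never flagged", {
  set.seed(72)
  flagged <- sum(vapply(1:200, function(i) {
    !is.na(first_outlier_cycle(rnorm(33, 0, 3), alpha = 0.01))
  }, logical(1)))
  expect_lte(flagged / 200, 0.05)
})

test_that("FDM finds the inflection of a logistic and is shift-invariant", {
  t <- 1:33
  logistic <- 2000 / (1 + exp(-0.6 * (t - 15)))  # inflection at cycle 15
  f <- fdm_cycle(logistic)
  expect_equal(f$cycle, 15L)
  expect_equal(f$rfu, logistic[15])
  shifted <- fdm_cycle(logistic + 500)
  expect_equal(shifted$cycle, f$cycle)
  expect_error(fdm_cycle(c(1, 2)), "at least 3")
  # ties break to the earliest cycle
  expect_equal(fdm_cycle(c(0, 1, 2, 3, 4, 4, 4))$cycle, 2L)
})

test_that("FDM cycles of a simulated plate sit near the half-plateau", {
  plate <- simulate_plate(n_sets = 2, noise_sd = 0, seed = 1)
  fdm <- fdm_cycles(plate)
  # logistic damping puts the steepest rise around plateau/2
  expect_true(all(fdm$rfu > 600 & fdm$rfu < 1500))
})

test_that("stable_region_scan is flat at the true F0 and drifts otherwise", {
  rfu <- oracle_curve(0.004, 0.8, 20)
  scan <- stable_region_scan(rfu, f0 = 0.004, sd_tol = 0.01)
  expect_equal(scan$e_values$e, rep(0.8, 20), tolerance = 1e-12)
  expect_equal(scan$stable_span, c(1, 20))
  expect_lt(scan$span_sd, 1e-12)

  wrong <- stable_region_scan(rfu, f0 = 0.008)
  # closed form under a doubled candidate: E(i) = 1.8 / 2^(1/i) - 1
  expect_equal(wrong$e_values$e, 1.8 / 2^(1 / (1:20)) - 1, tolerance = 1e-12)
  expect_true(all(diff(wrong$e_values$e) > 0))

  expect_error(stable_region_scan(rep(-1, 10), f0 = 1), "positive")
  expect_error(stable_region_scan(rfu, f0 = 0), "positive")
})

test_that("window clamping raises a lower bound inside the noise band", {
  plate <- simulate_plate(n_sets = 4, seed = 33)
  np <- noise_profile(plate, cycles = 1:5)
  expect_warning(w <- clamp_window(c(2, 180), np), "clamped")
  expect_gte(w[1], abs(np$min))
  expect_silent(clamp_window(c(50, 180), np))
})

test_that("boundary grid search matches a direct precision run and flags infeasible windows", {
  plate <- simulate_plate(seed = 34)
  grid <- tibble::tibble(lower = c(20, 1e6), upper = c(180, 1e7))
  res <- boundary_grid_search(plate, grid, seed = 9)
  expect_true(res$feasible[res$lower == 20])
  expect_false(res$feasible[res$lower == 1e6])

  est <- suppressWarnings(plate_efficiencies(plate, window = c(20, 180)))
  direct <- monte_carlo_precision(est, seed = 9)
  expect_equal(res$sd[res$lower == 20], direct$sd, tolerance = 1e-12)

  # deterministic under a fixed seed
  res2 <- boundary_grid_search(plate, grid, seed = 9)
  expect_identical(res, res2)
})

test_that("noiseless identical replicate sets give zero boundary-search SD", {
  plate <- simulate_plate(n_sets = 6, noise_sd = 0,
                          set_offsets = rep(0L, 6), seed = 1)
  res <- boundary_grid_search(plate, tibble::tibble(lower = 20, upper = 180),
                              seed = 2)
  expect_equal(res$sd, 0, tolerance = 1e-12)
})
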