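test_that("F0 back-calculation is exact on noiseless curves", {
  plate <- plate_from_curves(list(oracle_curve(1, 0.8, 20)))
  f0 <- estimate_f0(plate, e = 0.8, window = c(20, 180))
  expect_equal(f0$f0, 1, tolerance = 1e-12)

  plate2 <- simulate_plate(e_true = 0.8, f0 = 0.004, n_sets = 1, steps = 0,
                           plateau = Inf, noise_sd = 0, seed = 1)
  f02 <- estimate_f0(plate2, e = 0.8, window = c(20, 180))
  expect_equal(f02$f0, 0.004, tolerance = 1e-12)
  expect_gte(f02$n_readings, 3)
})

test_that("F0 scales linearly with the readings", {
  plate <- simulate_plate(n_sets = 1, seed = 111)
  f1 <- estimate_f0(plate, e = 0.8)
  scaled <- qpcr_plate(dplyr::mutate(plate$fluorescence, rfu = rfu * 3),
                       plate$layout, base = plate$base)
  f3 <- estimate_f0(scaled, e = 0.8, window = c(20 * 3, 180 * 3))
  common <- intersect(f1$well, f3$well)
  expect_equal(f3$f0[match(common, f3$well)],
               3 * f1$f0[match(common, f1$well)], tolerance = 1e-12)
})

test_that("requested wells without in-window readings are an error", {
  plate <- plate_from_curves(list(rep(1, 10)))
  expect_error(estimate_f0(plate, e = 0.8, wells = "A1"), "no in-window")
  expect_error(estimate_f0(plate, e = -1), "> -1")
})

test_that("expression ratios follow the amplification-factor closed form", {
  expect_equal(pfaffl_ratio(0.9, 20, 20), 1)
  expect_equal(pfaffl_ratio(0.882, 20, 21), 1.882, tolerance = 1e-12)
  # reciprocity
  set.seed(112)
  for (i in 1:20) {
    e <- runif(1, 0.5, 1); a <- runif(1, 15, 30); b <- runif(1, 15, 30)
    expect_equal(pfaffl_ratio(e, a, b) * pfaffl_ratio(e, b, a), 1,
                 tolerance = 1e-12)
  }
  expect_error(pfaffl_ratio(-1.2, 20, 21), "> -1")
})

test_that("identical noiseless replicates give unit maximal-error ratios", {
  plate <- simulate_plate(n_sets = 4, noise_sd = 0, plateau = Inf,
                          set_offsets = rep(0L, 4), seed = 1)
  cq <- call_cq(plate, 31.07)
  res <- max_error_analysis(plate, e = 0.8, method = "both", cq = cq)
  expect_equal(res$ratio, c(1, 1), tolerance = 1e-9)
  expect_equal(res$error_pct, c(0, 0), tolerance = 1e-6)
})

test_that("maximal-error ratios exceed 1 on noisy replicates", {
  plate <- simulate_plate(seed = 113)
  cq <- call_cq(plate, 31.07)
  res <- max_error_analysis(plate, e = 0.82, method = "both", cq = cq)
  expect_true(all(res$ratio >= 1))
  expect_equal(res$method, c("pfaffl_cq", "f0_based"))
  expect_error(max_error_analysis(plate, e = 0.8, wells = "A1", cq = cq),
               "at least 2")
})

test_that("noiseless dilution-accuracy folds equal the known ratios exactly", {
  plate <- simulate_plate(noise_sd = 0, plateau = Inf, seed = 1)
  cq <- call_cq(plate, 31.07)
  acc <- dilution_accuracy_table(plate, cq = cq)
  g <- acc$groups
  expect_equal(g$expected_fold, c(1, 2, 8, 32))
  expect_equal(g$fold_f0, g$expected_fold, tolerance = 1e-9)
  expect_equal(g$fold_cq, g$expected_fold, tolerance = 1e-9)
  expect_equal(acc$avg_error_f0_pct, 0, tolerance = 1e-6)
  expect_equal(acc$avg_error_cq_pct, 0, tolerance = 1e-6)
  # reference group against itself
  expect_equal(g$fold_f0[1], 1, tolerance = 1e-12)
  expect_equal(g$error_f0_pct[1], 0, tolerance = 1e-9)
})

test_that("the error convention is (observed - expected) / observed", {
  # reproduce the convention on a constructed observed/expected pair
  obs <- 2.513; exp_fold <- 2
  expect_equal(100 * (obs - exp_fold) / obs, 20.41384, tolerance = 1e-4)
  plate <- simulate_plate(seed = 114)
  acc <- dilution_accuracy_table(plate, cq = call_cq(plate, 31.07))
  g <- acc$groups[-1, ]
  expect_equal(g$error_f0_pct,
               100 * (g$fold_f0 - g$expected_fold) / g$fold_f0,
               tolerance = 1e-12)
})
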