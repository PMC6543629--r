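test_that("pairwise efficiency reproduces closed-form cases", {
  # exact doubling on one curve
  expect_equal(pairwise_efficiency(100, 20, 0, 200, 21, 0), 1)
  # a 2-fold dilution catching up in one cycle implies perfect doubling
  expect_equal(pairwise_efficiency(150, 20, 0, 150, 21, 1), 1)
  # ten-fold base
  expect_equal(pairwise_efficiency(50, 10, 0, 500, 11, 0, base = 10), 9,
               tolerance = 1e-12)
  expect_error(pairwise_efficiency(100, 20, 0, 200, 20, 1), "same cycle")
  expect_error(pairwise_efficiency(-1, 20, 0, 200, 21, 0), "positive")
})

test_that("pairwise efficiency is orientation-invariant", {
  set.seed(81)
  for (i in 1:50) {
    f <- exp(runif(2, -2, 6)); cyc <- sample(1:30, 2); d <- sample(0:5, 2,
                                                                   replace = TRUE)
    ab <- pairwise_efficiency(f[1], cyc[1], d[1], f[2], cyc[2], d[2])
    ba <- pairwise_efficiency(f[2], cyc[2], d[2], f[1], cyc[1], d[1])
    expect_equal(ab, ba, tolerance = 1e-12)
  }
})

test_that("relabelling a well one step less dilute with b-fold readings leaves cross-well pairs unchanged", {
  # under the model F = F0 b^-D (1+E)^i, multiplying a curve's readings
  # by b is the same physical sample relabelled with D - 1
  set.seed(82)
  rd <- random_readings(20)
  rd2 <- rd
  target <- rd2$well == rd2$well[1]
  rd2$rfu[target] <- rd2$rfu[target] * 2
  rd2$dilution_step[target] <- rd2$dilution_step[target] - 1L
  a1 <- enumerate_pairs(rd)
  a2 <- enumerate_pairs(rd2)
  cross <- a1$well_a != a1$well_b
  expect_equal(a2$value[cross], a1$value[cross], tolerance = 1e-12)
})

test_that("pair enumeration matches the brute-force oracle and the count formula", {
  set.seed(83)
  for (i in 1:30) {
    rd <- random_readings(40)
    arr <- enumerate_pairs(rd)
    oracle <- oracle_pairs(rd)
    expect_equal(nrow(arr), oracle$count)
    expect_equal(sort(arr$value), sort(oracle$values), tolerance = 1e-12)
    n_c <- table(rd$cycle)
    expect_equal(nrow(arr), choose(nrow(rd), 2) - sum(choose(n_c, 2)))
  }
  expect_error(enumerate_pairs(random_readings(40)[1, ]), "at least 2")
})

test_that("cross-well-only mode drops same-curve pairs", {
  set.seed(84)
  rd <- random_readings(30)
  arr <- enumerate_pairs(rd, cross_well_only = TRUE)
  oracle <- oracle_pairs(rd, cross_well_only = TRUE)
  expect_equal(nrow(arr), oracle$count)
  expect_true(all(arr$well_a != arr$well_b))
})

test_that("all pairs of a noiseless plate recover the true efficiency", {
  plate <- simulate_plate(e_true = 0.8, n_sets = 1, plateau = Inf,
                          noise_sd = 0, seed = 1)
  rd <- admit_readings(plate, plate$layout$set_id[1], window = c(20, 180))
  arr <- enumerate_pairs(rd)
  expect_gt(nrow(arr), 50)
  expect_true(all(abs(arr$value - 0.8) < 1e-12))
})

test_that("admitted readings respect the closed window and carry steps", {
  plate <- simulate_plate(n_sets = 1, noise_sd = 0, plateau = Inf, seed = 1)
  rd <- admit_readings(plate, plate$layout$set_id[1], window = c(20, 180))
  expect_true(all(rd$rfu >= 20 & rd$rfu <= 180))
  expect_setequal(unique(rd$dilution_step), 0:5)
  # a reading exactly on the boundary is admitted
  pl2 <- plate_from_curves(list(c(10, 20, 40, 80, 160, 320)))
  rd2 <- admit_readings(pl2, "S1", window = c(20, 160))
  expect_setequal(rd2$rfu, c(20, 40, 80, 160))
  expect_error(admit_readings(plate, plate$layout$set_id[1],
                              window = c(1e8, 1e9)), "empty window")
})

test_that("moment diagnostics use the bias-corrected conventions", {
  sym <- rep(c(1, -1), 50)
  st <- suppressWarnings(distribution_stats(sym))
  expect_equal(st$skew, 0, tolerance = 1e-12)
  expect_equal(st$skew, e1071::skewness(sym, type = 2))
  expect_equal(st$kurtosis_excess, e1071::kurtosis(sym, type = 2))

  set.seed(85)
  z <- rnorm(1e4)
  stz <- distribution_stats(z, bin_width = 0.5)
  expect_lt(abs(stz$skew), 0.1)
  expect_lt(abs(stz$kurtosis_excess), 0.2)
  expect_false(stz$normal_rejected)
})

test_that("histogram bins are half-open and anchored at zero", {
  st <- suppressWarnings(distribution_stats(c(0.07, 0.05, 0.1, 0.149)))
  h <- st$histogram
  expect_equal(h$lower, c(0.05, 0.10))
  expect_equal(h$count, c(2L, 2L))  # 0.05, 0.07 | 0.10, 0.149
  expect_warning(distribution_stats(runif(10)), "Fewer than 50")
})

test_that("outlier exclusion removes distant values and tightens the mean", {
  set.seed(86)
  vals <- c(0.80 + runif(100, -0.01, 0.01), rep(2, 3))
  arr <- structure(tibble::tibble(value = vals), base = 2,
                   class = c("pairwise_e_array", "tbl_df", "tbl", "data.frame"))
  est <- exclude_outliers(arr)
  expect_equal(est$n_total, 103)
  expect_equal(est$n_retained, 100)
  expect_lt(abs(est$e - 0.80), 0.005)
  expect_lte(est$excluded_high_cutoff, 2)
  # spread never increases
  retained <- vals[vals <= est$excluded_high_cutoff]
  expect_lte(sd(retained), sd(vals))
})

test_that("concentrated or sparse distributions are left untouched", {
  one_bin <- structure(tibble::tibble(value = rep(0.81, 60)), base = 2,
                       class = c("pairwise_e_array", "tbl_df", "tbl",
                                 "data.frame"))
  est <- exclude_outliers(one_bin)
  expect_equal(est$n_retained, 60)
  expect_equal(est$e, 0.81)

  sparse <- structure(tibble::tibble(value = seq(0, 3, length.out = 12)),
                      base = 2,
                      class = c("pairwise_e_array", "tbl_df", "tbl",
                                "data.frame"))
  expect_warning(est2 <- exclude_outliers(sparse), "too sparse")
  expect_equal(est2$n_retained, 12)
})

test_that("exclusion does not widen the retained spread on noisy sets", {
  for (s in 1:20) {
    plate <- simulate_plate(n_sets = 1, seed = 500 + s)
    est <- set_efficiency(plate, plate$layout$set_id[1])
    rd <- admit_readings(plate, plate$layout$set_id[1], window = c(20, 180))
    vals <- enumerate_pairs(rd)$value
    lo <- est$excluded_low_cutoff
    hi <- est$excluded_high_cutoff
    keep <- vals >= (if (is.na(lo)) -Inf else lo) &
      vals <= (if (is.na(hi)) Inf else hi)
    expect_lte(sd(vals[keep]), sd(vals))
  }
})

test_that("set_efficiency is exact on noiseless data and deterministic", {
  plate <- simulate_plate(e_true = 0.8, n_sets = 1, plateau = Inf,
                          noise_sd = 0, seed = 1)
  est <- set_efficiency(plate, plate$layout$set_id[1])
  expect_equal(est$e, 0.8, tolerance = 1e-12)
  expect_equal(est$n_retained, est$n_total)

  noisy <- simulate_plate(seed = 87)
  e1 <- set_efficiency(noisy, noisy$layout$set_id[1])
  e2 <- set_efficiency(noisy, noisy$layout$set_id[1])
  expect_identical(tidy(e1), tidy(e2))
  expect_equal(nrow(plate_efficiencies(noisy)), 16)
})
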