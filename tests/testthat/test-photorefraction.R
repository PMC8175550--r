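test_that("slope estimation is exact on a noiseless line", {
  p <- data.frame(position = 0:10, brightness = 2 * (0:10) + 5)
  fit <- estimate_slope(p)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  flat <- data.frame(position = 0:10, brightness = rep(3, 11))
  expect_equal(estimate_slope(flat)$slope, 0)
  expect_error(estimate_slope(data.frame(position = c(1, 1, 2),
                                         brightness = 1:3)), "increasing")
  expect_error(estimate_slope(p[1:2, ]), ">= 3")
})

test_that("refraction averaging is mean slope times the conversion factor", {
  expect_equal(average_refraction(rep(1, 100), 1.924), 1.924)
  expect_equal(average_refraction(rep(0, 10), 1.924), 0)
  expect_equal(average_refraction(c(1, 2, 3), 2), 4)
  expect_error(average_refraction(numeric(0), 2), "at least one")
  expect_error(average_refraction(1, 0), "non-zero")
  # linear in the factor and in each slope
  s <- c(0.3, -0.2, 1.1)
  expect_equal(average_refraction(s, 3), 3 * average_refraction(s, 1))
  expect_equal(average_refraction(2 * s, 1), 2 * average_refraction(s, 1))
})

test_that("calibration recovers the generating conversion factor", {
  powers <- c(-6, -2, 0, 4, 10)
  cc <- calibrate(powers, powers / 1.924)
  expect_equal(cc$factor, 1.924)
  expect_equal(cc$r_squared, 1)
  expect_equal(calibrate(powers, powers)$factor, 1)
  expect_error(calibrate(c(1, 1), c(1, 2)), "distinct")
  expect_error(calibrate(powers, rep(0.5, 5)), "identical")
})

test_that("noisy calibration stays within 5% and R-squared matches the residual formula", {
  powers <- c(-6, -2, 0, 4, 10)
  slopes <- lapply(seq_along(powers), function(k) {
    vapply(1:20, function(r) {
      p <- generate_pupil_profile(powers[k], 1.924, noise_sd = 0.05,
                                  seed = 1000L * k + r)
      estimate_slope(p)$slope
    }, numeric(1))
  })
  cc <- calibrate(powers, slopes)
  expect_lt(abs(cc$factor - 1.924) / 1.924, 0.05)
  # independent R^2: hand-computed regression through covariance formulas
  ms <- vapply(slopes, mean, numeric(1))
  beta <- sum((ms - mean(ms)) * (powers - mean(powers))) /
    sum((ms - mean(ms))^2)
  alpha <- mean(powers) - beta * mean(ms)
  r2 <- 1 - sum((powers - alpha - beta * ms)^2) /
    sum((powers - mean(powers))^2)
  expect_equal(cc$factor, beta)
  expect_equal(cc$r_squared, r2)
})

test_that("relative refraction subtracts the wild-type baseline", {
  expect_equal(relative_refraction(4, c(3, 5)), 0)
  expect_equal(relative_refraction(6, c(4, 4)), 2)
  # hyperopic shift positive, myopic negative
  expect_gt(relative_refraction(5, c(2, 2)), 0)
  expect_lt(relative_refraction(-1, c(2, 2)), 0)
  expect_error(relative_refraction(1, numeric(0)), "non-empty")
})

test_that("profile phenotypes classify as monofocal, bifocal or absent", {
  mono <- generate_pupil_profile(4, 2, noise_sd = 0)
  expect_equal(classify_profile(mono)$class, "monofocal")
  bif <- generate_pupil_profile(4, 2, variant = "bifocal", noise_sd = 0)
  out <- classify_profile(bif)
  expect_equal(out$class, "bifocal")
  expect_lt(abs(out$breakpoint - 0.5), 0.1)
  # a gradient-free, noise-dominated profile: the normalized global slope
  # falls below the absent threshold for most realizations
  abs_cls <- vapply(1:10, function(s) {
    p <- generate_pupil_profile(0, 2, n_points = 400L, variant = "absent",
                                noise_sd = 0.3, seed = s)
    classify_profile(p)$class
  }, character(1))
  expect_gte(sum(abs_cls == "absent"), 7)
  expect_false(any(abs_cls == "bifocal"))
})

test_that("classification is invariant to brightness offset and gain", {
  for (variant in c("monofocal", "bifocal")) {
    p <- generate_pupil_profile(4, 2, variant = variant, noise_sd = 0.02,
                                seed = 5)
    shifted <- p
    shifted$brightness <- 3.7 * p$brightness + 12
    expect_equal(classify_profile(shifted)$class, classify_profile(p)$class)
  }
})

test_that("short profiles fall back to monofocal/absent with a flag", {
  p <- generate_pupil_profile(4, 2, n_points = 5L, noise_sd = 0)
  out <- classify_profile(p)
  expect_true(out$flagged)
  expect_true(out$class %in% c("monofocal", "absent"))
})
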