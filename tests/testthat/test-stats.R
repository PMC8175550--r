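make_cohort <- function(wt_lengths, mut_lengths, value = 100) {
  n <- length(wt_lengths) + length(mut_lengths)
  data.frame(
    fish_id = rep(sprintf("f%02d", seq_len(n)), each = 2),
    genotype = rep(rep(c("WT", "mutant"),
                       c(length(wt_lengths), length(mut_lengths))), each = 2),
    eye = rep(c("left", "right"), n),
    body_length_mm = rep(c(wt_lengths, mut_lengths), each = 2),
    value = value + stats::rnorm(2 * n, sd = 1e-6))
}

test_that("size matching keeps WT fish within 10% of the mean mutant body length", {
  withr::with_seed(1, {
    co <- make_cohort(wt_lengths = c(18.0, 20.0, 21.9, 22.1),
                      mut_lengths = rep(20, 4))
    out <- size_match_controls(co)
    kept <- unique(out$body_length_mm[out$genotype == "WT"])
    expect_setequal(kept, c(18.0, 20.0, 21.9))   # 22.1 falls outside [18, 22]
    expect_equal(attr(out, "n_dropped_fish"), 1)
    # both eyes of a kept fish survive together
    expect_true(all(table(out$fish_id) == 2))
    # idempotent when every WT fish is already inside the band
    out2 <- size_match_controls(out)
    expect_equal(out2$fish_id, out$fish_id)
    only_wt <- co[co$genotype == "WT", ]
    expect_error(size_match_controls(only_wt), "mutant group is empty")
  })
})

test_that("the mixed model recovers a noiseless genotype effect exactly", {
  co <- generate_cohort(cohort_spec(effect = -47, sd_fish = 0,
                                    sd_residual = 0, n_per_group = 5))
  # a fully noiseless response is degenerate for REML; add negligible jitter
  co$value <- co$value + withr::with_seed(1, rnorm(nrow(co), sd = 1e-8))
  fit <- fit_random_intercept_lmm(co)
  expect_equal(fit$effect, -47, tolerance = 1e-6)
})

test_that("balanced designs match the closed-form fish-mean oracle", {
  for (seed in 1:5) {
    co <- generate_cohort(cohort_spec(effect = -47, seed = seed))
    fit <- fit_random_intercept_lmm(co)
    fish_means <- tapply(co$value, co$fish_id, mean)
    fish_geno <- tapply(as.character(co$genotype), co$fish_id, unique)
    oracle <- mean(fish_means[fish_geno == "mutant"]) -
      mean(fish_means[fish_geno == "WT"])
    expect_equal(fit$effect, unname(oracle), tolerance = 1e-6)
  }
})

test_that("the mixed model reduces to OLS when the between-fish variance is zero", {
  co <- generate_cohort(cohort_spec(effect = -30, sd_fish = 0,
                                    sd_residual = 12, seed = 4))
  fit <- fit_random_intercept_lmm(co)
  ols <- stats::lm(value ~ genotype, data = co)
  expect_equal(fit$effect, unname(coef(ols)["genotypemutant"]),
               tolerance = 0.02)
})

test_that("mixed-model variance components track the simulated design", {
  effs <- vapply(1:40, function(s) {
    fit <- fit_random_intercept_lmm(generate_cohort(cohort_spec(
      effect = -47, sd_fish = 15, sd_residual = 10, seed = s)))
    fit$effect
  }, numeric(1))
  sem <- stats::sd(effs) / sqrt(length(effs))
  expect_lt(abs(mean(effs) - (-47)), 3 * sem + 1)
  single <- fit_random_intercept_lmm(generate_cohort(cohort_spec(seed = 1)))
  expect_gt(single$sd_fish, 0)
  expect_gt(single$sd_residual, 0)
  expect_true(single$p_value > 0 && single$p_value <= 1)
})

test_that("one-genotype tables are rejected", {
  co <- generate_cohort(cohort_spec(n_per_group = 4))
  expect_error(fit_random_intercept_lmm(co[co$genotype == "WT", ]),
               ">= 2 fish")
})

test_that("Welch's F equals Welch's t squared for two groups", {
  withr::with_seed(7, {
    for (k in 1:5) {
      x <- rnorm(8 + k, sd = 1)
      y <- rnorm(15, mean = 0.8, sd = 3)
      res <- welch_anova(list(x, y))
      expect_equal(res$f, welch_t(x, y)^2, tolerance = 1e-12)
      tt <- t.test(x, y)   # Welch by default
      expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
      expect_equal(res$df2, unname(tt$parameter), tolerance = 1e-9)
    }
  })
})

test_that("Welch's ANOVA matches the textbook formula for three groups", {
  withr::with_seed(8, {
    groups <- list(rnorm(10, 0, 1), rnorm(14, 0.5, 2), rnorm(7, 1, 0.5))
    res <- welch_anova(groups)
    oracle <- welch_f_oracle(groups)
    expect_equal(res$f, oracle$f, tolerance = 1e-9)
    expect_equal(res$df1, oracle$df1)
    expect_equal(res$df2, oracle$df2, tolerance = 1e-6)
  })
})

test_that("identical groups give F = 0 and degenerate groups error", {
  g <- c(1, 2, 3, 4)
  expect_equal(welch_anova(list(g, g))$f, 0)
  expect_error(welch_anova(list(g)), ">= 2 groups")
  expect_error(welch_anova(list(g, rep(1, 4))), "zero variance")
  expect_error(welch_anova(list(g, 1)), "n >= 2")
})

test_that("the cross-sectional report analyzes each age independently", {
  ages <- c("1.5 mpf", "2 mpf", "3 mpf")
  effects <- c(-47, -48, -43)
  tabs <- lapply(seq_along(ages), function(k) {
    generate_cohort(cohort_spec(effect = effects[k], age_label = ages[k],
                                seed = 40 + k))
  })
  rep3 <- crosssectional_report(do.call(rbind, tabs))
  expect_equal(nrow(rep3), 3)
  expect_true(all(is.na(rep3$error)))
  expect_true(all(abs(rep3$effect - effects) < 12))  # ~2-3 SE at this design
  # an age with only WT fish is flagged; other ages unaffected
  broken <- tabs[[1]][tabs[[1]]$genotype == "WT", ]
  rep_mixed <- crosssectional_report(rbind(broken, tabs[[2]]))
  expect_false(is.na(rep_mixed$error[rep_mixed$age == "1.5 mpf"]))
  expect_true(is.na(rep_mixed$error[rep_mixed$age == "2 mpf"]))
  # single age equals a direct fit
  rep1 <- crosssectional_report(tabs[[1]], size_match = FALSE)
  direct <- fit_random_intercept_lmm(tabs[[1]])
  expect_equal(rep1$effect, direct$effect)
})
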