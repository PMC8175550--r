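test_that("phantom compartments occupy optical-path extents = thickness * index", {
  spec <- eye_phantom_spec(thickness_um = c(cornea = 30, anterior_chamber = 40,
                                            lens = 500, vitreous_chamber = 300,
                                            retina = 180))
  b <- generate_bscan(spec)
  lens <- b$truth[b$truth$compartment == "lens", ]
  expect_equal(lens$optical_px, 350)              # 500 * 1.4 / 2
  expect_equal(lens$end_px - lens$start_px + 1L, 350L)
  # image bands carry the configured reflectivities
  expect_equal(unique(b$image[lens$start_px:lens$end_px, 1]), 0.20)
})

test_that("unit refractive indices make optical extents equal physical extents", {
  ones <- setNames(rep(1, 5), names(wt_thickness))
  b <- generate_bscan(eye_phantom_spec(thickness_um = wt_thickness,
                                       index = ones, pixel_depth_um = 1))
  expect_equal(b$truth$optical_um, unname(wt_thickness))
})

test_that("ground-truth optical total equals sum of thickness times tissue index", {
  b <- generate_bscan(eye_phantom_spec(thickness_um = exact_thickness,
                                       pixel_depth_um = 1))
  expect_equal(sum(b$truth$optical_um),
               sum(exact_thickness * default_refractive_indices()))
})

test_that("noiseless phantoms satisfy the optical/physical round trip within a pixel", {
  for (seed in 1:3) {
    spec <- eye_phantom_spec(thickness_um = wt_thickness * (0.9 + 0.1 * seed),
                             seed = seed)
    b <- generate_bscan(spec)
    back <- b$truth$optical_um / b$truth$index
    expect_true(all(abs(back - b$truth$physical_um) <= spec$pixel_depth_um))
  }
})

test_that("sub-pixel compartments are rejected as degenerate phantoms", {
  thin <- wt_thickness
  thin["anterior_chamber"] <- 0.5
  expect_error(generate_bscan(eye_phantom_spec(thickness_um = thin)),
               "degenerate")
})

test_that("pupil profiles encode the designed slope exactly", {
  p <- generate_pupil_profile(refraction = -4, factor = 2, noise_sd = 0)
  expect_equal(estimate_slope(p)$slope, -2)
  p0 <- generate_pupil_profile(refraction = 0, factor = 2, noise_sd = 0)
  expect_equal(estimate_slope(p0)$slope, 0)
  p1 <- generate_pupil_profile(refraction = 1.924, factor = 1.924,
                               noise_sd = 0)
  expect_equal(estimate_slope(p1)$slope, 1)
  expect_error(generate_pupil_profile(1, 0), "non-zero")
  expect_error(generate_pupil_profile(1, 2, n_points = 2), ">= 3")
})

test_that("sawtooth traces have exact slow-phase slope and recorded resets", {
  tr <- generate_okr_trace(okr_trace_spec(gain = 0.6, duration_s = 10,
                                          noise_sd_deg = 0))
  expect_equal(tr$design$slow_velocity_dps, 12)
  expect_gt(length(tr$design$event_times_s), 0)
  flat <- generate_okr_trace(okr_trace_spec(gain = 0))
  expect_length(flat$design$event_times_s, 0)
  expect_equal(var(flat$angle_deg), 0)
  expect_error(generate_okr_trace(okr_trace_spec(saccade_rate_hz = 60)),
               "saccade rate")
})

test_that("ERG template reaches the designed B-wave amplitude after baseline removal", {
  e <- generate_erg_trace(erg_trace_spec(b_amplitude_uv = 200,
                                         baseline_uv = 50))
  corrected <- baseline_correct(e)
  expect_equal(max(corrected$voltage_uv), 200)
  z <- generate_erg_trace(erg_trace_spec(b_amplitude_uv = 0, baseline_uv = 50))
  expect_equal(var(z$voltage_uv), 0)   # baseline only, no response
  expect_error(generate_erg_trace(erg_trace_spec(interval_ms = 300)),
               "overlap")
})

test_that("lens images hit a target opaque fraction up to ring quantization", {
  li <- generate_lens_image(lens_image_spec(rings = nuclear_ring(),
                                            target_fraction = 0.25))
  expect_lt(abs(li$opaque_fraction - 0.25), 0.01)
  clear <- clear_lens(1)
  expect_equal(clear$opaque_fraction, 0)
  expect_error(generate_lens_image(lens_image_spec(
    rings = nuclear_ring(radius_frac = 0.1), target_fraction = 0.9)),
    "infeasible")
})

test_that("single-ring opaque fraction matches the analytic annulus/disk ratio", {
  r0 <- 0.5; w <- 8; R <- 50
  li <- generate_lens_image(lens_image_spec(lens_radius_px = R,
    rings = nuclear_ring(radius_frac = r0, width_px = w)))
  analytic <- 2 * r0 * (w / R)   # ((r0+w/2)^2 - (r0-w/2)^2) / R^2
  expect_lt(abs(li$opaque_fraction - analytic), 0.02)
})

test_that("noiseless cohorts carry the genotype effect exactly and seeds reproduce", {
  co <- generate_cohort(cohort_spec(effect = -47, sd_fish = 0,
                                    sd_residual = 0))
  diffs <- mean(co$value[co$genotype == "mutant"]) -
    mean(co$value[co$genotype == "WT"])
  expect_equal(diffs, -47)
  expect_true(all(table(co$fish_id) == 2))
})

test_that("all generators are pure functions of their spec and seed", {
  expect_identical(generate_bscan(eye_phantom_spec(noise = 0.05, seed = 9)),
                   generate_bscan(eye_phantom_spec(noise = 0.05, seed = 9)))
  expect_identical(generate_okr_trace(okr_trace_spec(noise_sd_deg = 1, seed = 9)),
                   generate_okr_trace(okr_trace_spec(noise_sd_deg = 1, seed = 9)))
  expect_identical(generate_erg_trace(erg_trace_spec(noise_sd_uv = 5, seed = 9)),
                   generate_erg_trace(erg_trace_spec(noise_sd_uv = 5, seed = 9)))
  expect_identical(generate_lens_image(lens_image_spec(seed = 9)),
                   generate_lens_image(lens_image_spec(seed = 9)))
  expect_identical(generate_cohort(cohort_spec(seed = 9)),
                   generate_cohort(cohort_spec(seed = 9)))
  # and distinct seeds change stochastic output
  expect_false(identical(generate_cohort(cohort_spec(seed = 9)),
                         generate_cohort(cohort_spec(seed = 10))))
})
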