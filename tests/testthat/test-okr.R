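test_that("fast-phase detection recovers the designed reset count and slow slopes", {
  tr <- generate_okr_trace(okr_trace_spec(gain = 0.6, duration_s = 10,
                                          noise_sd_deg = 0))
  seg <- detect_fast_phases(tr)
  expect_equal(nrow(seg$events), length(tr$design$event_times_s))
  expect_true(all(abs(seg$slow_intervals$velocity_dps - 12) < 0.5))
  expect_equal(unique(seg$events$direction), tr$design$event_direction)
})

test_that("a flat trace yields no events and one zero-velocity slow interval", {
  tr <- generate_okr_trace(okr_trace_spec(gain = 0, duration_s = 5))
  seg <- detect_fast_phases(tr)
  expect_equal(nrow(seg$events), 0)
  expect_equal(nrow(seg$slow_intervals), 1)
  expect_equal(seg$slow_intervals$velocity_dps, 0)
})

test_that("non-uniform sampling is rejected", {
  tr <- list(time_s = c(0, 0.01, 0.5, 0.6), angle_deg = rep(0, 4),
             drum_velocity_dps = 20)
  expect_error(detect_fast_phases(tr), "non-uniform")
})

test_that("optokinetic gain is eye velocity over drum velocity", {
  tr <- generate_okr_trace(okr_trace_spec(gain = 1, noise_sd_deg = 0))
  expect_equal(optokinetic_gain(detect_fast_phases(tr)), 1)
  tr6 <- generate_okr_trace(okr_trace_spec(gain = 0.6, noise_sd_deg = 0))
  expect_lt(abs(optokinetic_gain(detect_fast_phases(tr6)) - 0.6), 0.05)
  flat <- detect_fast_phases(generate_okr_trace(okr_trace_spec(gain = 0)))
  expect_equal(optokinetic_gain(flat), 0)
  # temporal stimulation: tracking still yields positive gain
  tt <- generate_okr_trace(okr_trace_spec(gain = 0.8, direction = "temporal",
                                          noise_sd_deg = 0))
  expect_gt(optokinetic_gain(detect_fast_phases(tt)), 0)
})

test_that("gain is invariant to angle offset and time shift", {
  tr <- generate_okr_trace(okr_trace_spec(gain = 0.7, noise_sd_deg = 0.1,
                                          seed = 3))
  g0 <- optokinetic_gain(detect_fast_phases(tr))
  shifted <- tr
  shifted$angle_deg <- tr$angle_deg + 33
  shifted$time_s <- tr$time_s + 5
  expect_equal(optokinetic_gain(detect_fast_phases(shifted)), g0)
})

test_that("ETM counts filter by direction and sum to the total event count", {
  tr <- generate_okr_trace(okr_trace_spec(gain = 0.8, duration_s = 30,
                                          noise_sd_deg = 0))
  seg <- detect_fast_phases(tr)
  # nasal slow phase: all resets are temporal
  n_nasal <- count_etms(seg, "nasal")
  n_temporal <- count_etms(seg, "temporal")
  expect_equal(n_nasal, 0)
  expect_equal(3 * (n_nasal + n_temporal), nrow(seg$events))
  expect_equal(count_etms(seg, "temporal", window_s = 30), nrow(seg$events))
  expect_error(count_etms(seg, "nasal", window_s = 60), "shorter")
})

test_that("the positive-response rule needs three consecutive cycles in both directions", {
  good <- detect_fast_phases(generate_okr_trace(okr_trace_spec(
    gain = 0.8, duration_s = 10, noise_sd_deg = 0)))
  poor <- detect_fast_phases(generate_okr_trace(okr_trace_spec(
    gain = 0.8, duration_s = 10, saccade_rate_hz = 0.1, noise_sd_deg = 0)))
  expect_true(okr_response_positive(good, good))
  expect_false(okr_response_positive(poor))        # < 3 events
  expect_false(okr_response_positive(good, poor))  # must hold in both directions
  # events present but separated by > 1 s gaps do not count as consecutive
  sparse <- detect_fast_phases(generate_okr_trace(okr_trace_spec(
    gain = 0.8, duration_s = 20, saccade_rate_hz = 0.3, noise_sd_deg = 0)))
  expect_false(okr_response_positive(sparse))
})

test_that("the acuity staircase returns the highest verified positive frequency", {
  r <- data.frame(frequency_cpd = c(0.15, 0.20, 0.25, 0.30, 0.30),
                  positive = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  out <- acuity_staircase(r)
  expect_equal(out$acuity_cpd, 0.25)
  expect_true(out$verified)
  expect_false(out$below_start)
  # unverified when the repeat is missing
  expect_false(acuity_staircase(r[1:4, ])$verified)
  # negative at the first frequency: flagged, acuity below the grid
  r0 <- data.frame(frequency_cpd = c(0.15, 0.15), positive = c(FALSE, FALSE))
  out0 <- acuity_staircase(r0)
  expect_true(out0$below_start)
  expect_true(is.na(out0$acuity_cpd))
  # the full published grid runs 0.15-0.40 cpd
  grid <- seq(0.15, 0.40, by = 0.05)
  rg <- data.frame(frequency_cpd = c(grid, 0.40),
                   positive = c(rep(TRUE, 5), FALSE, FALSE))
  expect_equal(acuity_staircase(rg)$acuity_cpd, 0.35)
  expect_error(acuity_staircase(data.frame(frequency_cpd = c(0.15, 0.27),
                                           positive = c(TRUE, FALSE))),
               "grid")
})
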