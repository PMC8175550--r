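#' Render a synthetic OCT B-scan of a layered zebrafish eye
#'
#' Builds a 2-D axial intensity image in which each ocular compartment
#' occupies a run of pixels whose optical-path extent equals its physical
#' thickness multiplied by its refractive index, rounded to the pixel grid.
#' Compartment boundaries appear as intensity steps; the retinal pigment
#' epithelium is rendered as the brightest band, whose rising edge is the
#' posterior landmark of the axial length.  Speckle is modelled as
#' multiplicative Gaussian noise.
#'
#' @param spec an [eye_phantom_spec()].
#' @return A list of class `bscan` with elements
#'   \describe{
#'     \item{image}{numeric matrix, rows = axial (Z) pixels, columns = A-scans.}
#'     \item{pixel_depth_um}{axial pixel depth of the optical path.}
#'     \item{truth}{ground-truth biometry table: per compartment the physical
#'       thickness, refractive index, rendered optical extent in pixels and
#'       micrometres, and start/end pixel.}
#'     \item{boundaries_px}{the six ground-truth boundary pixels (corneal
#'       apex through anterior RPE); a boundary pixel belongs to the
#'       posterior compartment.}
#'   }
#' @examples
#' b <- generate_bscan(eye_phantom_spec(noise = 0.05, seed = 7))
#' b$truth
#' @export
generate_bscan <- function(spec) {
  stopifnot(inherits(spec, "eye_phantom_spec"))
  optical_px <- round(spec$thickness_um * spec$index / spec$pixel_depth_um)
  if (any(optical_px < 1)) {
    stop_spec("degenerate phantom: a compartment is thinner than one pixel ",
              "after optical-path conversion")
  }
  rpe_px <- max(1, round(spec$rpe_um * spec$index[["retina"]] /
                           spec$pixel_depth_um))
  tail_px <- 10L
  n_z <- spec$background_px + sum(optical_px) + rpe_px + tail_px

  profile <- rep(spec$background_reflectivity, n_z)
  start <- spec$background_px + 1L
  starts <- integer(5L); ends <- integer(5L)
  for (k in seq_along(COMPARTMENTS)) {
    starts[k] <- start
    ends[k] <- start + optical_px[k] - 1L
    profile[starts[k]:ends[k]] <- spec$reflectivity[k]
    start <- ends[k] + 1L
  }
  rpe_start <- start
  profile[rpe_start:(rpe_start + rpe_px - 1L)] <- spec$rpe_reflectivity

  img <- matrix(profile, nrow = n_z, ncol = spec$width)
  if (spec$noise > 0) {
    img <- withr::with_seed(spec$seed, {
      img * (1 + spec$noise * matrix(stats::rnorm(n_z * spec$width),
                                     nrow = n_z))
    })
    img[img < 0] <- 0
  }

  truth <- data.frame(compartment = COMPARTMENTS,
                      physical_um = as.numeric(spec$thickness_um),
                      index = as.numeric(spec$index),
                      optical_px = as.integer(optical_px),
                      optical_um = as.numeric(optical_px) * spec$pixel_depth_um,
                      start_px = starts, end_px = ends,
                      row.names = NULL)
  boundaries <- c(starts, rpe_start)
  names(boundaries) <- c("corneal_apex", "cornea_ac", "ac_lens",
                         "lens_vitreous", "vitreous_retina", "anterior_rpe")
  structure(list(image = img, pixel_depth_um = spec$pixel_depth_um,
                 truth = truth, boundaries_px = boundaries),
            class = "bscan")
}

#' Generate a synthetic pupil brightness profile
#'
#' Eccentric photorefraction infers defocus from the slope of the
#' brightness gradient across the pupil.  This generator produces samples
#' following `intensity = baseline + (refraction / factor) * position +
#' noise` over a normalized pupil coordinate in \[0, 1\].  The `"bifocal"`
#' variant concatenates two half-profiles with opposite-signed slopes, and
#' the `"absent"` variant has zero designed slope (pair with a high
#' `noise_sd` to emulate an undetectable gradient).
#'
#' @param refraction refractive error in diopters that the profile encodes.
#' @param factor conversion factor in diopters per slope unit (non-zero);
#'   the designed slope is `refraction / factor`.
#' @param n_points number of samples across the pupil (>= 3).
#' @param noise_sd additive Gaussian brightness noise SD.
#' @param baseline baseline brightness.
#' @param variant `"monofocal"`, `"bifocal"` or `"absent"`.
#' @param seed integer random seed.
#' @return A data.frame of class `pupil_profile` with columns `position`
#'   and `brightness`, and attributes `designed_slope` and `variant`.
#' @examples
#' p <- generate_pupil_profile(refraction = 1.924, factor = 1.924, noise_sd = 0)
#' estimate_slope(p)$slope   # 1
#' @export
generate_pupil_profile <- function(refraction, factor, n_points = 50L,
                                   noise_sd = 0, baseline = 0.5,
                                   variant = c("monofocal", "bifocal", "absent"),
                                   seed = 1L) {
  variant <- match.arg(variant)
  if (factor == 0) stop_spec("'factor' must be non-zero")
  if (n_points < 3L) stop_spec("'n_points' must be >= 3 to fit a slope")
  position <- seq(0, 1, length.out = n_points)
  slope <- refraction / factor
  designed <- switch(variant,
    monofocal = slope * position,
    absent = rep(0, n_points),
    bifocal = {
      # two half-pupils of opposite defocus, apex at the pupil centre
      s <- abs(slope)
      ifelse(position <= 0.5, s * (0.5 - position), s * (position - 0.5))
    })
  brightness <- baseline + designed
  if (noise_sd > 0) {
    brightness <- withr::with_seed(seed,
      brightness + stats::rnorm(n_points, sd = noise_sd))
  }
  out <- data.frame(position = position, brightness = brightness)
  attr(out, "designed_slope") <- if (variant == "absent") 0 else slope
  attr(out, "variant") <- variant
  class(out) <- c("pupil_profile", "data.frame")
  out
}

#' Generate a synthetic sawtooth nystagmus trace
#'
#' The eye angle rises at `gain * drum_velocity` during slow phases and is
#' reset by a saccade of fixed amplitude at regular intervals; resets are
#' directed against the slow phase.  A gain of zero produces a flat trace
#' with no resets.  Designed event times, the slow-phase velocity, and the
#' trace metadata are recorded and never re-derived from samples.
#'
#' @param spec an [okr_trace_spec()].
#' @return A list of class `eye_trace` with elements `time_s`, `angle_deg`,
#'   `drum_velocity_dps`, `spatial_frequency_cpd`, `direction` (slow-phase
#'   direction), and `design` (list: `gain`, `slow_velocity_dps`,
#'   `event_times_s`, `event_direction`).
#' @examples
#' tr <- generate_okr_trace(okr_trace_spec(gain = 1, noise_sd_deg = 0))
#' @export
generate_okr_trace <- function(spec) {
  stopifnot(inherits(spec, "okr_trace_spec"))
  dt <- 1 / spec$frame_rate_hz
  n <- floor(spec$duration_s * spec$frame_rate_hz) + 1L
  time_s <- (seq_len(n) - 1L) * dt
  sgn <- if (spec$direction == "nasal") 1 else -1
  v_slow <- sgn * spec$gain * abs(spec$drum_velocity_dps)

  if (spec$gain > 0 && spec$saccade_rate_hz > 0) {
    period <- 1 / spec$saccade_rate_hz
    if (period <= 2 * dt) {
      stop_spec("saccade rate too high: no slow phase would span >= 2 frames")
    }
    # resets snapped to frame boundaries so slow-phase slopes stay exact
    event_times <- if (period <= spec$duration_s - dt) {
      seq(period, spec$duration_s - dt, by = period)
    } else numeric(0)
    event_frames <- round(event_times / dt)
    event_times <- event_frames * dt
  } else {
    event_times <- numeric(0)
    event_frames <- integer(0)
  }

  angle <- v_slow * time_s
  for (f in event_frames) {
    idx <- time_s >= (f + 0.5) * dt   # jump lands between frame f and f + 1
    angle[idx] <- angle[idx] - sgn * spec$saccade_amplitude_deg
  }
  if (spec$noise_sd_deg > 0) {
    angle <- withr::with_seed(spec$seed,
      angle + stats::rnorm(n, sd = spec$noise_sd_deg))
  }
  structure(list(time_s = time_s, angle_deg = angle,
                 drum_velocity_dps = sgn * abs(spec$drum_velocity_dps),
                 spatial_frequency_cpd = spec$spatial_frequency_cpd,
                 direction = spec$direction,
                 design = list(gain = spec$gain,
                               slow_velocity_dps = v_slow,
                               event_times_s = event_times,
                               event_direction = if (sgn > 0) "temporal" else "nasal")),
            class = "eye_trace")
}

# Difference-of-gamma ERG template evaluated at t ms after stimulus onset,
# scaled so its maximum over the given sample grid equals b_amplitude.
erg_template <- function(t_ms, a_amp, b_amp, tau_a, tau_b,
                         shape_a = 4, shape_b = 5) {
  gam <- function(t, k, theta) {
    g <- ifelse(t <= 0, 0, (t / ((k - 1) * theta))^(k - 1) *
                  exp(-(t - (k - 1) * theta) / theta))
    g
  }
  raw <- -a_amp * gam(t_ms, shape_a, tau_a / (shape_a - 1)) +
    (b_amp + a_amp) * gam(t_ms, shape_b, tau_b / (shape_b - 1))
  m <- max(raw)
  if (m <= 0) return(raw * 0)
  raw * (b_amp / m)
}

#' Generate a synthetic electroretinogram trace
#'
#' Superimposes, at each stimulus onset, a biphasic template (negative
#' A-wave lobe followed by a positive B-wave lobe, modelled as a difference
#' of gamma kernels) on a constant baseline offset, plus optional Gaussian
#' noise.  The template is rescaled so that in the noiseless case the
#' maximum of the baseline-corrected response equals the designed B-wave
#' amplitude exactly on the sample grid.
#'
#' @param spec an [erg_trace_spec()].
#' @return A list of class `erg_trace` with elements `time_ms`,
#'   `voltage_uv`, `onsets_ms`, `stimulus_ms`, `sampling_rate_hz`, and
#'   `design` (list with the designed `b_amplitude_uv`).
#' @examples
#' e <- generate_erg_trace(erg_trace_spec(b_amplitude_uv = 200))
#' @export
generate_erg_trace <- function(spec) {
  stopifnot(inherits(spec, "erg_trace_spec"))
  dt_ms <- 1000 / spec$sampling_rate_hz
  template_support_ms <- 1000
  if (spec$n_stimuli > 1L && spec$interval_ms < template_support_ms) {
    stop_spec("inter-stimulus interval shorter than the response template ",
              "support: responses would overlap")
  }
  total_ms <- spec$pre_stimulus_ms +
    (spec$n_stimuli - 1L) * spec$interval_ms + template_support_ms
  n <- floor(total_ms / dt_ms) + 1L
  time_ms <- (seq_len(n) - 1L) * dt_ms
  onsets <- spec$pre_stimulus_ms + (seq_len(spec$n_stimuli) - 1L) * spec$interval_ms
  onsets <- round(onsets / dt_ms) * dt_ms   # snap onsets to the sample grid

  v <- rep(spec$baseline_uv, n)
  rel <- time_ms - onsets[1L]
  shape <- erg_template(rel[rel >= 0 & rel <= template_support_ms],
                        spec$a_amplitude_uv, spec$b_amplitude_uv,
                        spec$tau_a_ms, spec$tau_b_ms)
  for (on in onsets) {
    i0 <- which(time_ms >= on)[1L]
    idx <- i0:min(n, i0 + length(shape) - 1L)
    v[idx] <- v[idx] + shape[seq_along(idx)]
  }
  if (spec$noise_sd_uv > 0) {
    v <- withr::with_seed(spec$seed, v + stats::rnorm(n, sd = spec$noise_sd_uv))
  }
  structure(list(time_ms = time_ms, voltage_uv = v, onsets_ms = onsets,
                 stimulus_ms = spec$stimulus_ms,
                 sampling_rate_hz = spec$sampling_rate_hz,
                 design = list(b_amplitude_uv = spec$b_amplitude_uv)),
            class = "erg_trace")
}

# Pixels whose centre-distance from the disk centre falls inside the
# annulus [r0 - w/2, r0 + w/2], restricted to the lens disk.
ring_pixel_count <- function(dist, radius, r0, w) {
  sum(dist <= radius & abs(dist - r0) <= w / 2)
}

#' Generate a synthetic coronal lens-section image
#'
#' Renders the lens as a bright disk on a darker background; nuclear
#' opacities are concentric rings of elevated intensity.  If the spec gives
#' a target opaque-pixel fraction, the ring width is solved on the pixel
#' grid so the rendered opaque mask covers that fraction of the lens disk
#' (up to one-ring quantization).  The ground-truth fraction reported is
#' always measured from the rendered mask.
#'
#' @param spec a [lens_image_spec()].
#' @return A list of class `lens_image` with elements `image` (numeric
#'   matrix in \[0, 1\]), `lens_mask` (logical matrix), `opaque_mask`
#'   (logical matrix of ground-truth ring pixels), `opaque_fraction`
#'   (ground truth, measured from the rendered mask), and `rings` (the ring
#'   table actually rendered).
#' @examples
#' li <- generate_lens_image(lens_image_spec(
#'   rings = data.frame(radius_frac = 0.4, width_px = 5, contrast = 0.3)))
#' li$opaque_fraction
#' @export
generate_lens_image <- function(spec) {
  stopifnot(inherits(spec, "lens_image_spec"))
  s <- spec$size
  centre <- (s + 1) / 2
  xy <- expand.grid(row = seq_len(s), col = seq_len(s))
  dist <- matrix(sqrt((xy$row - centre)^2 + (xy$col - centre)^2), nrow = s)
  lens_mask <- dist <= spec$lens_radius_px

  rings <- spec$rings
  if (!is.null(spec$target_fraction)) {
    target_px <- spec$target_fraction * sum(lens_mask)
    r0 <- rings$radius_frac[1L] * spec$lens_radius_px
    w_max <- 2 * min(r0, spec$lens_radius_px - r0) + 2
    grid_w <- seq(0, w_max, by = 0.25)
    counts <- vapply(grid_w, function(w)
      ring_pixel_count(dist, spec$lens_radius_px, r0, w), numeric(1))
    if (max(counts) < target_px - 1) {
      stop_spec("infeasible target fraction: ring at this radius cannot ",
                "cover the requested share of the lens disk")
    }
    rings$width_px[1L] <- grid_w[which.min(abs(counts - target_px))]
  }

  img <- matrix(spec$background, nrow = s, ncol = s)
  img[lens_mask] <- spec$cortex
  opaque <- matrix(FALSE, nrow = s, ncol = s)
  if (!is.null(rings)) {
    for (k in seq_len(nrow(rings))) {
      r0 <- rings$radius_frac[k] * spec$lens_radius_px
      in_ring <- lens_mask & abs(dist - r0) <= rings$width_px[k] / 2
      img[in_ring] <- spec$cortex * (1 + rings$contrast[k])
      if (rings$contrast[k] > 0) opaque <- opaque | in_ring
    }
  }
  if (spec$noise_sd > 0) {
    img <- withr::with_seed(spec$seed,
      img + matrix(stats::rnorm(s * s, sd = spec$noise_sd), nrow = s))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  structure(list(image = img, lens_mask = lens_mask, opaque_mask = opaque,
                 opaque_fraction = sum(opaque) / sum(lens_mask),
                 rings = rings),
            class = "lens_image")
}

#' Simulate a paired-eye cohort table
#'
#' Per fish, draws a body length and a random intercept; per eye, a
#' residual.  The outcome is `grand_mean + effect * I(mutant) + intercept +
#' residual`, matching the random-intercept linear mixed model used in the
#' analysis, so the genotype effect is recoverable by parameter recovery.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame of class `cohort_table` with columns `fish_id`,
#'   `genotype` (factor, WT reference), `eye`, `age`, `body_length_mm`,
#'   `outcome`, `value`, and attribute `design` recording the simulated
#'   effect.
#' @examples
#' head(generate_cohort(cohort_spec(seed = 3)))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  withr::with_seed(spec$seed, {
    genotype <- rep(c("WT", "mutant"), each = n)
    fish_id <- sprintf("fish%03d", seq_len(2L * n))
    body <- stats::rnorm(2L * n,
                         mean = rep(spec$body_length_mean_mm, each = n),
                         sd = rep(spec$body_length_sd_mm, each = n))
    u <- stats::rnorm(2L * n, sd = spec$sd_fish)
    fish_mean <- spec$grand_mean + spec$effect * (genotype == "mutant") + u
    out <- data.frame(
      fish_id = rep(fish_id, each = 2L),
      genotype = factor(rep(genotype, each = 2L), levels = c("WT", "mutant")),
      eye = rep(c("left", "right"), times = 2L * n),
      age = spec$age_label,
      body_length_mm = rep(body, each = 2L),
      outcome = spec$outcome,
      value = rep(fish_mean, each = 2L) +
        stats::rnorm(4L * n, sd = spec$sd_residual))
    attr(out, "design") <- list(effect = spec$effect,
                                grand_mean = spec$grand_mean)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
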