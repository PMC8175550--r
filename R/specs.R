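#' @keywords internal
"_PACKAGE"

COMPARTMENTS <- c("cornea", "anterior_chamber", "lens", "vitreous_chamber", "retina")

stop_spec <- function(...) stop(..., call. = FALSE)

check_num <- function(x, name, len = 1L, min = -Inf, max = Inf,
                      strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop_spec(sprintf("'%s' must be a numeric vector of length %d", name, len))
  }
  if (any(x < min) || any(x > max) || (strict_min && any(x <= min))) {
    stop_spec(sprintf("'%s' out of range", name))
  }
  invisible(x)
}

#' Specification of a layered-eye OCT phantom
#'
#' Describes a five-compartment zebrafish eye (cornea, anterior chamber,
#' lens, vitreous chamber, neural retina) by physical thickness, refractive
#' index and mean reflectivity per compartment.  The phantom generator
#' renders each compartment as a run of axial pixels whose optical-path
#' extent equals physical thickness times refractive index, so biometry can
#' be validated by parameter recovery.
#'
#' @param thickness_um named numeric vector of physical thicknesses in
#'   micrometres for the five compartments, anterior to posterior.
#' @param index named numeric vector of refractive indices (dimensionless,
#'   all >= 1) for the same compartments; defaults to
#'   [default_refractive_indices()].
#' @param reflectivity named numeric vector of mean reflectivities
#'   (arbitrary units in (0, 1]).  The retinal pigment epithelium is always
#'   rendered as the brightest band and is configured separately.
#' @param noise speckle noise level as a fraction of mean intensity
#'   (multiplicative Gaussian); >= 0.
#' @param pixel_depth_um axial pixel depth of the optical path in
#'   micrometres (instrument default 2).
#' @param width number of A-scan columns in the rendered B-scan.
#' @param background_px number of background pixels rendered anterior to the
#'   corneal apex.
#' @param rpe_um physical thickness of the rendered RPE band in micrometres
#'   (posterior to the axial-length endpoint).
#' @param background_reflectivity,rpe_reflectivity intensities of the
#'   background and of the hyperreflective RPE band.
#' @param seed integer random seed used for the speckle noise.
#' @return An object of class `eye_phantom_spec`.
#' @seealso [generate_bscan()]
#' @export
eye_phantom_spec <- function(thickness_um = c(cornea = 20, anterior_chamber = 5,
                                              lens = 495, vitreous_chamber = 300,
                                              retina = 180),
                             index = default_refractive_indices(),
                             reflectivity = c(cornea = 0.35,
                                              anterior_chamber = 0.10,
                                              lens = 0.20,
                                              vitreous_chamber = 0.08,
                                              retina = 0.45),
                             noise = 0,
                             pixel_depth_um = 2,
                             width = 64L,
                             background_px = 20L,
                             rpe_um = 25,
                             background_reflectivity = 0.05,
                             rpe_reflectivity = 1.0,
                             seed = 1L) {
  thickness_um <- thickness_um[COMPARTMENTS]
  index <- index[COMPARTMENTS]
  reflectivity <- reflectivity[COMPARTMENTS]
  check_num(thickness_um, "thickness_um", 5L, min = 0, strict_min = TRUE)
  check_num(index, "index", 5L, min = 1)
  check_num(reflectivity, "reflectivity", 5L, min = 0, strict_min = TRUE)
  check_num(noise, "noise", min = 0)
  check_num(pixel_depth_um, "pixel_depth_um", min = 0, strict_min = TRUE)
  check_num(rpe_um, "rpe_um", min = 0, strict_min = TRUE)
  structure(list(thickness_um = thickness_um, index = index,
                 reflectivity = reflectivity, noise = noise,
                 pixel_depth_um = pixel_depth_um, width = as.integer(width),
                 background_px = as.integer(background_px), rpe_um = rpe_um,
                 background_reflectivity = background_reflectivity,
                 rpe_reflectivity = rpe_reflectivity,
                 seed = as.integer(seed)),
            class = "eye_phantom_spec")
}

#' Specification of a synthetic optokinetic nystagmus trace
#'
#' A sawtooth eye-angle model: slow phases track the drum at
#' `gain * drum_velocity` and are interrupted by fast resets (saccades) of
#' fixed amplitude at a fixed rate.  With `gain = 0` the eye does not track
#' and no resets are generated.
#'
#' @param gain true optokinetic gain (eye velocity / drum velocity), >= 0.
#' @param drum_velocity_dps drum velocity in degrees per second (non-zero;
#'   default 20, the standard stimulus speed).
#' @param frame_rate_hz sampling rate in frames per second (default 96,
#'   the camera rate).
#' @param duration_s trace duration in seconds.
#' @param saccade_amplitude_deg amplitude of each fast reset in degrees.
#' @param saccade_rate_hz number of resets per second.
#' @param noise_sd_deg additive Gaussian angular noise SD in degrees.
#' @param direction direction of the slow (tracking) phase, `"nasal"`
#'   (positive angles) or `"temporal"`.
#' @param spatial_frequency_cpd grating spatial frequency metadata in
#'   cycles per degree.
#' @param seed integer random seed.
#' @return An object of class `okr_trace_spec`.
#' @seealso [generate_okr_trace()]
#' @export
okr_trace_spec <- function(gain = 0.8, drum_velocity_dps = 20,
                           frame_rate_hz = 96, duration_s = 30,
                           saccade_amplitude_deg = 10, saccade_rate_hz = 0.8,
                           noise_sd_deg = 0, direction = c("nasal", "temporal"),
                           spatial_frequency_cpd = 0.15, seed = 1L) {
  direction <- match.arg(direction)
  check_num(gain, "gain", min = 0)
  check_num(frame_rate_hz, "frame_rate_hz", min = 0, strict_min = TRUE)
  check_num(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_num(noise_sd_deg, "noise_sd_deg", min = 0)
  if (!is.numeric(drum_velocity_dps) || drum_velocity_dps == 0) {
    stop_spec("'drum_velocity_dps' must be non-zero")
  }
  structure(list(gain = gain, drum_velocity_dps = drum_velocity_dps,
                 frame_rate_hz = frame_rate_hz, duration_s = duration_s,
                 saccade_amplitude_deg = saccade_amplitude_deg,
                 saccade_rate_hz = saccade_rate_hz,
                 noise_sd_deg = noise_sd_deg, direction = direction,
                 spatial_frequency_cpd = spatial_frequency_cpd,
                 seed = as.integer(seed)),
            class = "okr_trace_spec")
}

#' Specification of a synthetic electroretinogram trace
#'
#' Each light stimulus evokes a biphasic response modelled as a difference
#' of two gamma kernels: a negative A-wave lobe followed by a positive
#' B-wave lobe.  The template is scaled so that, in the noiseless case, the
#' maximum of the baseline-corrected response equals `b_amplitude_uv`.
#'
#' @param sampling_rate_hz sampling rate in Hz.
#' @param pre_stimulus_ms pre-stimulus baseline duration in ms (>= 50, the
#'   length of the baseline-correction window).
#' @param n_stimuli number of light stimuli.
#' @param interval_ms inter-stimulus interval in ms (protocol default 8000).
#' @param stimulus_ms stimulus duration in ms (protocol default 100).
#' @param a_amplitude_uv depth of the negative lobe, in microvolts, before
#'   template rescaling (shape parameter).
#' @param b_amplitude_uv designed maximal B-wave amplitude in microvolts
#'   after baseline correction (>= 0).
#' @param tau_a_ms,tau_b_ms time constants of the two gamma lobes in ms.
#' @param baseline_uv constant baseline offset in microvolts.
#' @param noise_sd_uv additive Gaussian noise SD in microvolts.
#' @param seed integer random seed.
#' @return An object of class `erg_trace_spec`.
#' @seealso [generate_erg_trace()]
#' @export
erg_trace_spec <- function(sampling_rate_hz = 1000, pre_stimulus_ms = 200,
                           n_stimuli = 2L, interval_ms = 8000,
                           stimulus_ms = 100, a_amplitude_uv = 50,
                           b_amplitude_uv = 200, tau_a_ms = 15, tau_b_ms = 40,
                           baseline_uv = 0, noise_sd_uv = 0, seed = 1L) {
  check_num(pre_stimulus_ms, "pre_stimulus_ms", min = 50)
  check_num(b_amplitude_uv, "b_amplitude_uv", min = 0)
  check_num(noise_sd_uv, "noise_sd_uv", min = 0)
  check_num(sampling_rate_hz, "sampling_rate_hz", min = 0, strict_min = TRUE)
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 pre_stimulus_ms = pre_stimulus_ms,
                 n_stimuli = as.integer(n_stimuli), interval_ms = interval_ms,
                 stimulus_ms = stimulus_ms, a_amplitude_uv = a_amplitude_uv,
                 b_amplitude_uv = b_amplitude_uv, tau_a_ms = tau_a_ms,
                 tau_b_ms = tau_b_ms, baseline_uv = baseline_uv,
                 noise_sd_uv = noise_sd_uv, seed = as.integer(seed)),
            class = "erg_trace_spec")
}

#' Specification of a synthetic coronal lens-section image
#'
#' Renders a bright lens disk on a darker background, optionally carrying
#' concentric ring opacities that emulate opaque nuclear fiber structures.
#' Either explicit rings or a target opaque-pixel fraction may be given; in
#' the latter case the ring width is solved so the rendered opaque mask
#' covers the target fraction of the lens disk up to ring quantization.
#'
#' @param size image side length in pixels (square image).
#' @param lens_radius_px lens disk radius in pixels (< `size / 2`).
#' @param background,cortex intensities of the background and of the lens
#'   cortex, in (0, 1).
#' @param rings a data.frame with columns `radius_frac` (ring centre radius
#'   as a fraction of the lens radius, in (0, 1)), `width_px` (ring width in
#'   pixels) and `contrast` (relative intensity elevation above the cortex,
#'   >= 0), or `NULL` for a clear lens.
#' @param target_fraction target opaque-pixel fraction of the lens disk in
#'   (0, 1), or `NULL`.  When given, `rings` must contain exactly one row
#'   whose `width_px` is solved for.
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param seed integer random seed.
#' @return An object of class `lens_image_spec`.
#' @seealso [generate_lens_image()]
#' @export
lens_image_spec <- function(size = 128L, lens_radius_px = 50,
                            background = 0.10, cortex = 0.45,
                            rings = NULL, target_fraction = NULL,
                            noise_sd = 0.02, seed = 1L) {
  check_num(lens_radius_px, "lens_radius_px", min = 0, strict_min = TRUE)
  if (lens_radius_px >= size / 2) {
    stop_spec("'lens_radius_px' must be smaller than half the image size")
  }
  if (!is.null(rings)) {
    stopifnot(is.data.frame(rings),
              all(c("radius_frac", "width_px", "contrast") %in% names(rings)))
    if (any(rings$radius_frac <= 0) || any(rings$radius_frac >= 1)) {
      stop_spec("ring 'radius_frac' values must lie in (0, 1)")
    }
    if (any(rings$contrast < 0)) stop_spec("ring 'contrast' must be >= 0")
  }
  if (!is.null(target_fraction)) {
    check_num(target_fraction, "target_fraction", min = 0, max = 1)
    if (is.null(rings) || nrow(rings) != 1L) {
      stop_spec("'target_fraction' requires exactly one ring row")
    }
  }
  check_num(noise_sd, "noise_sd", min = 0)
  structure(list(size = as.integer(size), lens_radius_px = lens_radius_px,
                 background = background, cortex = cortex, rings = rings,
                 target_fraction = target_fraction, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "lens_image_spec")
}

#' Specification of a synthetic two-eye cohort
#'
#' Simulates a paired-eye study: each fish contributes two eyes whose
#' measurements share a per-fish random intercept, and mutants carry a
#' fixed genotype effect, matching the random-intercept mixed model used
#' for analysis.
#'
#' @param n_per_group number of fish per genotype group.
#' @param effect genotype (mutant minus wild-type) effect on the outcome,
#'   in outcome units (micrometres, diopters, ...).
#' @param grand_mean wild-type mean of the outcome.
#' @param sd_fish between-fish SD (random-intercept SD), >= 0.
#' @param sd_residual within-fish residual SD (between eyes), >= 0.
#' @param body_length_mean_mm,body_length_sd_mm body-length distribution in
#'   millimetres; a length-2 vector gives per-group (WT, mutant) values.
#' @param age_label age annotation carried into the table (e.g. "1.5 mpf").
#' @param outcome name of the simulated outcome column metadata.
#' @param seed integer random seed.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_per_group = 20L, effect = -47, grand_mean = 1000,
                        sd_fish = 15, sd_residual = 10,
                        body_length_mean_mm = 20, body_length_sd_mm = 1,
                        age_label = "1.5 mpf", outcome = "axial_length_um",
                        seed = 1L) {
  check_num(sd_fish, "sd_fish", min = 0)
  check_num(sd_residual, "sd_residual", min = 0)
  if (n_per_group < 1L) stop_spec("'n_per_group' must be >= 1")
  blm <- rep_len(body_length_mean_mm, 2L)
  bls <- rep_len(body_length_sd_mm, 2L)
  check_num(bls, "body_length_sd_mm", 2L, min = 0)
  structure(list(n_per_group = as.integer(n_per_group), effect = effect,
                 grand_mean = grand_mean, sd_fish = sd_fish,
                 sd_residual = sd_residual, body_length_mean_mm = blm,
                 body_length_sd_mm = bls, age_label = age_label,
                 outcome = outcome, seed = as.integer(seed)),
            class = "cohort_spec")
}
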