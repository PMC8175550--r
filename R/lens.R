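#' Between-class-variance-maximizing threshold of a sample vector
#'
#' Classical bimodal-histogram (Otsu) threshold computed from a 256-bin
#' histogram of the supplied intensities; used to binarize lens sections
#' into opaque and clear pixels.  Exposed so the choice of threshold is
#' inspectable.
#'
#' @param x numeric vector of intensities.
#' @param n_bins number of histogram bins.
#' @return The threshold value (intensity units); pixels strictly above it
#'   are called opaque.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1L])
  breaks <- seq(r[1L], r[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  breaks[which.max(sigma_b) + 1L]
}

as_lens <- function(image, lens_mask) {
  if (inherits(image, "lens_image")) {
    list(image = image$image,
         mask = if (is.null(lens_mask)) image$lens_mask else lens_mask)
  } else {
    if (is.null(lens_mask)) stop_spec("'lens_mask' is required")
    list(image = as.matrix(image), mask = lens_mask)
  }
}

#' Opaque-pixel ratio of a coronal lens section
#'
#' Computes an automatic global threshold (bimodal-histogram method)
#' restricted to the lens mask and reports the fraction of lens pixels
#' above it.
#'
#' Before accepting the split, a bimodality guard requires the two class
#' means to be separated by at least `min_separation` pooled within-class
#' standard deviations; a clear lens whose histogram is a single noise
#' mode would otherwise be cut at its mean and half its pixels mislabelled
#' opaque.  When the guard trips the ratio is reported as 0 and flagged.
#'
#' @param image a `lens_image` (see [generate_lens_image()]) or a numeric
#'   matrix.
#' @param lens_mask logical matrix selecting lens pixels; taken from the
#'   `lens_image` when omitted.
#' @param min_separation minimum class-mean separation in pooled
#'   within-class SDs (default 3).
#' @return A list of class `opacity_result`: `n_lens_px`, `n_opaque_px`,
#'   `ratio`, `threshold`, `constant` (TRUE with a warning flag when the
#'   lens is uniform and the ratio is reported as 0), `weak_bimodality`.
#' @examples
#' li <- generate_lens_image(lens_image_spec(
#'   rings = data.frame(radius_frac = 0.4, width_px = 6, contrast = 0.3)))
#' opacity_ratio(li)$ratio
#' @export
opacity_ratio <- function(image, lens_mask = NULL, min_separation = 3) {
  z <- as_lens(image, lens_mask)
  px <- z$image[z$mask]
  if (length(px) == 0L) stop_spec("empty lens mask")
  if (diff(range(px)) == 0) {
    return(structure(list(n_lens_px = length(px), n_opaque_px = 0L,
                          ratio = 0, threshold = px[1L], constant = TRUE,
                          weak_bimodality = TRUE),
                     class = "opacity_result"))
  }
  thr <- otsu_threshold(px)
  lo <- px[px <= thr]
  hi <- px[px > thr]
  pooled <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
                   max(1L, length(px) - 2L))
  weak <- length(hi) == 0L || length(lo) == 0L ||
    (mean(hi) - mean(lo)) < min_separation * pooled
  n_op <- if (weak) 0L else length(hi)
  structure(list(n_lens_px = length(px), n_opaque_px = n_op,
                 ratio = n_op / length(px), threshold = thr,
                 constant = FALSE, weak_bimodality = weak),
            class = "opacity_result")
}

radial_profile <- function(image, mask) {
  idx <- which(mask, arr.ind = TRUE)
  centre <- colMeans(idx)
  ci <- round(centre)
  if (!mask[ci[1L], ci[2L]]) stop_spec("lens centroid falls outside the mask")
  d <- sqrt((idx[, 1L] - centre[1L])^2 + (idx[, 2L] - centre[2L])^2)
  radius <- max(d)
  bin <- pmin(floor(d) + 1L, ceiling(radius))
  vals <- image[mask]
  prof <- vapply(split(vals, bin), mean, numeric(1))
  r <- (as.integer(names(prof)) - 0.5) / radius
  list(r_frac = r, intensity = unname(prof), radius_px = radius,
       centre = centre)
}

running_median <- function(x, half = 7L) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Detect a nuclear ring opacity in a coronal lens section
#'
#' Computes the radial mean-intensity profile about the lens centroid and
#' scores the strongest elevation over a running-median local baseline at
#' interior radius fractions (0.1-0.8).  The score is normalized by the
#' lens-to-background intensity step, making the call invariant to global
#' affine brightness/contrast transforms; when no background pixels are
#' available the local baseline itself is the denominator and the result
#' is flagged.  A lens is called cataractous when the score reaches
#' `contrast_threshold` — the operational counterpart of a clearly visible
#' nuclear ring structure.
#'
#' @param image a `lens_image` or numeric matrix.
#' @param lens_mask logical lens mask (from the `lens_image` when omitted).
#' @param contrast_threshold minimum ring contrast score for a cataract
#'   call (default 0.10).
#' @return A list of class `cataract_call`: `cataractous`, `score`,
#'   `ring_radius_frac`, `flagged`.
#' @examples
#' li <- generate_lens_image(lens_image_spec(
#'   rings = data.frame(radius_frac = 0.4, width_px = 5, contrast = 0.3)))
#' detect_nuclear_ring(li)$cataractous
#' @export
detect_nuclear_ring <- function(image, lens_mask = NULL,
                                contrast_threshold = 0.10) {
  z <- as_lens(image, lens_mask)
  if (!any(z$mask)) stop_spec("empty lens mask")
  prof <- radial_profile(z$image, z$mask)
  base <- running_median(prof$intensity)
  outside <- z$image[!z$mask]
  flagged <- length(outside) == 0L
  denom <- if (flagged) base else (base - stats::median(outside))
  denom[denom <= 0] <- NA_real_
  score_r <- (prof$intensity - base) / denom
  interior <- prof$r_frac >= 0.1 & prof$r_frac <= 0.8
  score_r[!interior | !is.finite(score_r)] <- -Inf
  k <- which.max(score_r)
  score <- max(score_r[is.finite(score_r)], 0)
  structure(list(cataractous = score >= contrast_threshold,
                 score = score,
                 ring_radius_frac = if (score > 0) prof$r_frac[k] else NA_real_,
                 flagged = flagged),
            class = "cataract_call")
}

#' Cataract prevalence in percent
#'
#' @param calls list of `cataract_call` objects (or a logical vector).
#' @return Prevalence as an integer percent, rounded half-up.
#' @examples
#' prevalence(c(rep(TRUE, 22), rep(FALSE, 2)))  # 92
#' @export
prevalence <- function(calls) {
  flags <- if (is.logical(calls)) calls else {
    vapply(calls, function(x) isTRUE(x$cataractous), logical(1))
  }
  if (length(flags) == 0L) stop_spec("no cataract calls supplied")
  floor(100 * mean(flags) + 0.5)
}

#' Mutant-minus-wild-type cataract prevalence difference
#'
#' @param mutant_calls,wt_calls lists of `cataract_call` objects or
#'   logical vectors (both non-empty).
#' @return Difference in percentage points.
#' @export
prevalence_difference <- function(mutant_calls, wt_calls) {
  prevalence(mutant_calls) - prevalence(wt_calls)
}

#' Percent transmission loss through an isolated lens
#'
#' @param incident incident light intensity (> 0).
#' @param transmitted transmitted intensity (0 <= transmitted <= incident).
#' @param wavelength one of `"365 nm"` (UV), `"940 nm"` (IR) or
#'   `"380-760 nm"` (broad-spectrum visible).
#' @return A list of class `transmission_result`: `wavelength`,
#'   `percent_loss`.
#' @examples
#' transmission_loss(1, 0.8, "940 nm")$percent_loss  # 20
#' @export
transmission_loss <- function(incident, transmitted,
                              wavelength = c("365 nm", "940 nm", "380-760 nm")) {
  wavelength <- match.arg(wavelength)
  if (incident <= 0) stop_spec("incident intensity must be > 0")
  if (transmitted < 0 || transmitted > incident) {
    stop_spec("transmitted intensity must lie in [0, incident]")
  }
  structure(list(wavelength = wavelength,
                 percent_loss = 100 * (1 - transmitted / incident)),
            class = "transmission_result")
}
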