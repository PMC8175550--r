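#' Tissue refractive indices for zebrafish ocular compartments
#'
#' Scalar refractive indices used to convert OCT optical path lengths into
#' physical dimensions: cornea 1.33, anterior chamber 1.34, lens 1.4 (the
#' gradient index of the spherical zebrafish lens collapsed to a single
#' equivalent value), vitreous chamber 1.34, neural retina 1.38.
#'
#' @return Named numeric vector over the five compartments.
#' @export
default_refractive_indices <- function() {
  c(cornea = 1.33, anterior_chamber = 1.34, lens = 1.4,
    vitreous_chamber = 1.34, retina = 1.38)
}

check_indices <- function(indices) {
  if (!is.numeric(indices) || is.null(names(indices)) ||
      !setequal(names(indices), COMPARTMENTS)) {
    stop_spec("'indices' must be a named numeric vector over the five ",
              "ocular compartments")
  }
  if (any(indices < 1)) stop_spec("refractive indices must be >= 1")
  indices[COMPARTMENTS]
}

#' Convert an optical path length to a physical length
#'
#' OCT measures optical path (geometric path times refractive index); the
#' physical length is recovered by dividing by the tissue's refractive
#' index.
#'
#' @param optical_um optical path length in micrometres (>= 0).
#' @param n refractive index (>= 1).
#' @return Physical length in micrometres.
#' @examples
#' optical_to_physical(700, 1.4)  # 500
#' @export
optical_to_physical <- function(optical_um, n) {
  if (any(n < 1)) stop_spec("refractive index must be >= 1")
  if (any(optical_um < 0)) stop_spec("optical length must be >= 0")
  optical_um / n
}

# Weighted centroid of the above-half-max |gradient| inside a search
# window; returns the boundary pixel (first pixel of the posterior
# compartment).  `d` is diff(profile), so a step between pixels b-1 and b
# peaks at index b-1.
locate_step <- function(d, lo, hi, sign = 0) {
  idx <- max(1L, lo):min(length(d), hi)
  g <- d[idx]
  if (sign > 0) g[g < 0] <- 0
  if (sign < 0) g[g > 0] <- 0
  g <- abs(g)
  if (max(g) <= 0) return(NA_real_)
  keep <- g >= 0.5 * max(g)
  round(sum(idx[keep] * g[keep]) / sum(g[keep])) + 1L
}

#' Segment the six axial boundaries of an eye B-scan
#'
#' Works on the column-averaged A-scan of the image (or a single supplied
#' column).  The anterior-RPE boundary is located as the strongest rising
#' intensity edge (the rising edge of the hyperreflective melanin-rich
#' band) and the corneal apex as the first prominent rising edge; the four
#' interior boundaries are found as the intensity-step extrema nearest to a
#' prior layout, given as cumulative optical fractions of the apex-to-RPE
#' span.  Manually marked boundaries may be passed through instead via
#' `manual`.
#'
#' @param bscan a `bscan` object (see [generate_bscan()]) or a numeric
#'   matrix with rows along the optical axis.
#' @param pixel_depth_um axial pixel depth in micrometres; taken from the
#'   `bscan` object when available.
#' @param column optional column index: segment a single A-scan instead of
#'   the column average.
#' @param prior_fractions cumulative optical-path fractions (length 4,
#'   strictly increasing in (0, 1)) of the four interior boundaries within
#'   the apex-to-RPE span; defaults to the layout implied by
#'   [eye_phantom_spec()] defaults.
#' @param smooth_px moving-average half-width (pixels) applied to the
#'   A-scan before edge detection; 0 disables smoothing.
#' @param manual optional numeric vector of six boundary pixels marked
#'   manually; validated and passed through unchanged.
#' @return A list of class `axial_segmentation` with `boundaries_px` (named
#'   length-6 vector) and `pixel_depth_um`.
#' @examples
#' b <- generate_bscan(eye_phantom_spec())
#' segment_axial_boundaries(b)$boundaries_px
#' @export
segment_axial_boundaries <- function(bscan, pixel_depth_um = NULL,
                                     column = NULL, prior_fractions = NULL,
                                     smooth_px = 0, manual = NULL) {
  if (inherits(bscan, "bscan")) {
    img <- bscan$image
    if (is.null(pixel_depth_um)) pixel_depth_um <- bscan$pixel_depth_um
  } else {
    img <- as.matrix(bscan)
  }
  if (is.null(pixel_depth_um)) {
    stop_spec("'pixel_depth_um' is required when 'bscan' is a bare matrix")
  }
  bnames <- c("corneal_apex", "cornea_ac", "ac_lens", "lens_vitreous",
              "vitreous_retina", "anterior_rpe")
  if (!is.null(manual)) {
    if (length(manual) != 6L || any(diff(manual) <= 0)) {
      stop_spec("'manual' must give 6 strictly increasing boundary pixels")
    }
    b <- as.numeric(manual); names(b) <- bnames
    return(structure(list(boundaries_px = b, pixel_depth_um = pixel_depth_um),
                     class = "axial_segmentation"))
  }

  profile <- if (is.null(column)) rowMeans(img) else img[, column]
  if (smooth_px > 0) {
    k <- 2L * as.integer(smooth_px) + 1L
    profile <- as.numeric(stats::filter(profile, rep(1 / k, k), sides = 2))
    profile <- profile[!is.na(profile)]
  }
  d <- diff(profile)
  if (sum(abs(d) > 0.08 * max(abs(d))) < 6L) {
    stop_spec("segmentation failure: fewer resolvable intensity ",
              "transitions than boundaries")
  }

  # anchors: RPE rising edge = global max positive gradient; apex = first
  # prominent rising edge before it
  rpe <- which.max(d) + 1L
  pos <- which(d > 0.4 * max(d))
  pos <- pos[pos < rpe - 2L]
  if (length(pos) == 0L) stop_spec("segmentation failure: corneal apex not found")
  apex <- locate_step(d, pos[1L] - 2L, pos[1L] + 2L, sign = +1)

  if (is.null(prior_fractions)) {
    def <- eye_phantom_spec()
    opt <- def$thickness_um * def$index
    prior_fractions <- cumsum(opt)[1:4] / sum(opt)
  }
  if (length(prior_fractions) != 4L || any(diff(prior_fractions) <= 0) ||
      any(prior_fractions <= 0) || any(prior_fractions >= 1)) {
    stop_spec("'prior_fractions' must be 4 strictly increasing values in (0, 1)")
  }
  span <- rpe - apex
  priors <- apex + prior_fractions * span
  all_pos <- c(apex, priors, rpe)
  inner <- vapply(seq_len(4L), function(k) {
    half <- max(1, floor(min(all_pos[k + 1L] - all_pos[k],
                             all_pos[k + 2L] - all_pos[k + 1L]) / 2))
    locate_step(d, round(priors[k] - half) - 1L, round(priors[k] + half) - 1L)
  }, numeric(1))

  b <- c(apex, inner, rpe)
  names(b) <- bnames
  if (anyNA(b) || any(diff(b) <= 0)) {
    stop_spec("segmentation failure: boundaries not strictly increasing")
  }
  structure(list(boundaries_px = b, pixel_depth_um = pixel_depth_um),
            class = "axial_segmentation")
}

#' Compute ocular biometry from an axial segmentation
#'
#' Per compartment, the physical thickness is the boundary gap in pixels
#' times the pixel depth, divided by the tissue refractive index.  The
#' axial length is the sum of the five physical compartment thicknesses
#' (corneal apex to anterior RPE).
#'
#' @param seg an `axial_segmentation` (see [segment_axial_boundaries()]).
#' @param indices named refractive-index vector; defaults to
#'   [default_refractive_indices()].
#' @return A list of class `biometry_result`: `table` (per-compartment
#'   optical and physical extents in micrometres) and `axial_length_um`.
#' @examples
#' b <- generate_bscan(eye_phantom_spec())
#' compute_biometry(segment_axial_boundaries(b))$axial_length_um
#' @export
compute_biometry <- function(seg, indices = default_refractive_indices()) {
  stopifnot(inherits(seg, "axial_segmentation"))
  indices <- check_indices(indices)
  gaps_px <- diff(seg$boundaries_px)
  optical_um <- as.numeric(gaps_px) * seg$pixel_depth_um
  physical_um <- optical_to_physical(optical_um, as.numeric(indices))
  table <- data.frame(compartment = COMPARTMENTS,
                      gap_px = as.numeric(gaps_px),
                      optical_um = optical_um,
                      index = as.numeric(indices),
                      physical_um = physical_um,
                      row.names = NULL)
  structure(list(table = table, axial_length_um = sum(physical_um)),
            class = "biometry_result")
}

#' Percent change of a mutant mean relative to a wild-type mean
#'
#' @param mutant_mean,wt_mean group means on the same scale; `wt_mean`
#'   must be non-zero.
#' @return `100 * (mutant_mean - wt_mean) / wt_mean`.
#' @examples
#' percent_change(1070, 1000)  # 7
#' @export
percent_change <- function(mutant_mean, wt_mean) {
  if (any(wt_mean == 0)) stop_spec("wild-type mean must be non-zero")
  100 * (mutant_mean - wt_mean) / wt_mean
}
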