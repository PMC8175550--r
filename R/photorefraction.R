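as_profile <- function(profile) {
  if (inherits(profile, "pupil_profile") || is.data.frame(profile)) {
    stopifnot(all(c("position", "brightness") %in% names(profile)))
    profile
  } else {
    stop_spec("'profile' must be a data.frame with 'position' and 'brightness'")
  }
}

#' Estimate the pupil brightness-gradient slope
#'
#' Ordinary least-squares line through (position, brightness); the slope of
#' this gradient is the raw photorefraction measurement that a calibrated
#' conversion factor turns into a refractive error.
#'
#' @param profile a pupil profile: data.frame with `position` (strictly
#'   increasing) and `brightness`.
#' @return List with `slope`, `intercept` and `r_squared`.
#' @examples
#' p <- data.frame(position = 0:10, brightness = 2 * (0:10) + 5)
#' estimate_slope(p)$slope  # 2
#' @export
estimate_slope <- function(profile) {
  profile <- as_profile(profile)
  if (nrow(profile) < 3L) stop_spec("need >= 3 samples to fit a slope")
  if (any(diff(profile$position) <= 0)) {
    stop_spec("positions must be strictly increasing")
  }
  fit <- stats::lm(brightness ~ position, data = profile)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((profile$brightness - mean(profile$brightness))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2)
}

#' Average replicate slopes into a refractive error
#'
#' The instrument takes many independent slope measurements per eye (100 in
#' the standard protocol); their mean, multiplied by the calibration
#' conversion factor, is the refractive error in diopters.
#'
#' @param slopes numeric vector of replicate slope measurements (>= 1).
#' @param factor conversion factor in diopters per slope unit (non-zero).
#' @return Refractive error in diopters.
#' @examples
#' average_refraction(c(1, 2, 3), 2)  # 4
#' @export
average_refraction <- function(slopes, factor) {
  if (length(slopes) < 1L) stop_spec("need at least one slope")
  if (factor == 0) stop_spec("'factor' must be non-zero")
  mean(slopes) * factor
}

#' Calibrate the slope-to-diopter conversion factor with trial lenses
#'
#' Regresses lens power on the mean measured slope per lens; the regression
#' slope is the conversion factor (diopters per slope unit) and the
#' coefficient of determination reports calibration quality.
#'
#' @param lens_powers numeric vector of trial-lens powers in diopters
#'   (>= 2 distinct values).
#' @param slopes list of numeric vectors (replicate slopes per lens) or a
#'   numeric vector of one mean slope per lens, aligned with
#'   `lens_powers`.
#' @return A list of class `calibration_curve`: `lens_powers`,
#'   `mean_slopes`, `factor` (D per slope unit), `intercept`, `r_squared`.
#' @examples
#' powers <- c(-6, -2, 0, 4, 10)
#' calibrate(powers, powers / 1.924)$factor  # 1.924
#' @export
calibrate <- function(lens_powers, slopes) {
  if (length(unique(lens_powers)) < 2L) {
    stop_spec("need >= 2 distinct lens powers")
  }
  mean_slopes <- if (is.list(slopes)) {
    vapply(slopes, mean, numeric(1))
  } else {
    as.numeric(slopes)
  }
  if (length(mean_slopes) != length(lens_powers)) {
    stop_spec("'slopes' must align with 'lens_powers'")
  }
  if (length(unique(mean_slopes)) == 1L) {
    stop_spec("all slopes identical: conversion factor undefined")
  }
  fit <- stats::lm(lens_powers ~ mean_slopes)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((lens_powers - mean(lens_powers))^2)
  structure(list(lens_powers = lens_powers, mean_slopes = mean_slopes,
                 factor = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = 1 - ss_res / ss_tot),
            class = "calibration_curve")
}

#' Relative refractive error versus the wild-type baseline
#'
#' Small eyes reflect infrared light from the nerve-fiber layer rather than
#' the photoreceptors, shifting all absolute readings hyperopically (the
#' small-eye retinoscopic artifact).  Relative refraction removes this
#' shared offset by subtracting the mean wild-type refractive error;
#' positive values are hyperopic shifts, negative myopic.
#'
#' @param mutant_re numeric vector of mutant refractive errors in diopters.
#' @param wt_re numeric vector of wild-type refractive errors (non-empty).
#' @return Numeric vector: each mutant RE minus `mean(wt_re)`.
#' @examples
#' relative_refraction(6, c(3, 5))  # 2
#' @export
relative_refraction <- function(mutant_re, wt_re) {
  if (length(wt_re) < 1L) stop_spec("wild-type group must be non-empty")
  mutant_re - mean(wt_re)
}

fit_line_rss <- function(x, y) {
  X <- cbind(1, x)
  fit <- stats::lm.fit(X, y)
  list(slope = unname(fit$coefficients[2L]), rss = sum(fit$residuals^2))
}

#' Classify a pupil brightness profile phenotype
#'
#' Brightness and position are first normalized to \[0, 1\] so thresholds
#' are unit-free and invariant to brightness offset and gain.  A single
#' global line and the best two-segment piecewise line (breakpoint scanned
#' over interior samples) are fitted; the profile is called `"bifocal"`
#' when the two segment slopes have opposite signs and the piecewise fit
#' reduces the residual sum of squares by at least `split_gain`,
#' `"absent"` when the global normalized slope magnitude is below
#' `slope_threshold` without such a split, and `"monofocal"` otherwise.
#'
#' @param profile a pupil profile (>= 6 samples for the piecewise fit;
#'   with fewer, only monofocal/absent are distinguished and the result is
#'   flagged).
#' @param slope_threshold absent-gradient threshold on the normalized
#'   slope per pupil width (default 0.05).
#' @param split_gain minimum fractional residual-sum-of-squares reduction
#'   required to call a bifocal split (default 0.5).
#' @return List with `class` (one of `"monofocal"`, `"bifocal"`,
#'   `"absent"`), `global_slope` (normalized), `breakpoint` (position
#'   fraction, bifocal only, else `NA`), `rss_gain`, and `flagged`.
#' @examples
#' p <- generate_pupil_profile(2, 2, variant = "bifocal")
#' classify_profile(p)$class  # "bifocal"
#' @export
classify_profile <- function(profile, slope_threshold = 0.05,
                             split_gain = 0.5) {
  profile <- as_profile(profile)
  n <- nrow(profile)
  if (n < 3L) stop_spec("need >= 3 samples")
  x <- profile$position
  x <- (x - min(x)) / (max(x) - min(x))
  b <- profile$brightness
  rng <- max(b) - min(b)
  b <- if (rng > 0) (b - min(b)) / rng else rep(0, n)

  global <- fit_line_rss(x, b)
  breakpoint <- NA_real_
  rss_gain <- 0
  flagged <- n < 6L
  if (!flagged && global$rss > .Machine$double.eps * n) {
    best <- NULL
    for (k in 3:(n - 3L)) {
      left <- fit_line_rss(x[1:k], b[1:k])
      right <- fit_line_rss(x[(k + 1):n], b[(k + 1):n])
      rss2 <- left$rss + right$rss
      if (is.null(best) || rss2 < best$rss2) {
        best <- list(k = k, rss2 = rss2, s1 = left$slope, s2 = right$slope)
      }
    }
    rss_gain <- 1 - best$rss2 / global$rss
    if (rss_gain >= split_gain && sign(best$s1) * sign(best$s2) < 0) {
      breakpoint <- x[best$k]
      return(list(class = "bifocal", global_slope = global$slope,
                  breakpoint = breakpoint, rss_gain = rss_gain,
                  flagged = FALSE))
    }
  }
  cls <- if (abs(global$slope) < slope_threshold) "absent" else "monofocal"
  list(class = cls, global_slope = global$slope, breakpoint = NA_real_,
       rss_gain = rss_gain, flagged = flagged)
}
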