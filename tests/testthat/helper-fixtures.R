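# shared fixture builders for the test suite

wt_thickness <- c(cornea = 20, anterior_chamber = 5, lens = 495,
                  vitreous_chamber = 300, retina = 180)

# thicknesses chosen so thickness * index / pixel_depth is integral at
# pixel depth 1, making optical extents quantization-free
exact_thickness <- c(cornea = 100, anterior_chamber = 100, lens = 100,
                     vitreous_chamber = 100, retina = 100)

nuclear_ring <- function(radius_frac = 0.4, width_px = 5, contrast = 0.3) {
  data.frame(radius_frac = radius_frac, width_px = width_px,
             contrast = contrast)
}

ringed_lens <- function(seed, contrast = 0.3, radius_frac = 0.4) {
  generate_lens_image(lens_image_spec(
    rings = nuclear_ring(radius_frac = radius_frac, contrast = contrast),
    seed = seed))
}

clear_lens <- function(seed) {
  generate_lens_image(lens_image_spec(seed = seed))
}

# Welch's t statistic for two samples, by the textbook formula
welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# Welch's F for k groups, by the textbook formula (independent oracle)
welch_f_oracle <- function(groups) {
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  w <- n / v
  mw <- sum(w * m) / sum(w)
  k <- length(groups)
  a <- sum(w * (m - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (n - 1)) / (k^2 - 1)
  list(f = a / (1 + 2 * lam * (k - 2)), df1 = k - 1, df2 = 1 / (3 * lam))
}
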