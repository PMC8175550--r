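---
title: "Methods: ocular phenotyping of zebrafish eyes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ocular phenotyping of zebrafish eyes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfocular)
```

This vignette documents the models behind each analysis stage, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## OCT biometry

An OCT A-scan measures *optical* path length — geometric distance times
the tissue's refractive index. The biometry model is therefore simply

$$d_{\text{physical}} = \frac{\text{gap}_{\text{px}} \cdot
  \Delta z}{n_{\text{tissue}}},$$

applied per compartment between six axial boundaries (corneal apex,
cornea/aqueous, aqueous/lens, lens/vitreous, vitreous/retina, anterior
RPE), with axial length the sum of the five compartments. The indices are
scalars — cornea 1.33, aqueous and vitreous 1.34, lens 1.4, retina 1.38 —
with the lens's gradient index collapsed to its single equivalent value;
no group-index/phase-index distinction is made. `pixel_depth_um` defaults
to 2 µm, the axial sampling of the instrument class being modelled.

**Boundary convention.** A boundary pixel belongs to the posterior
compartment (half-open intervals), so compartment gaps sum exactly to the
apex-to-RPE span.

**Automated segmentation.** Borders in such recordings are classically
marked by hand, and `segment_axial_boundaries(manual = ...)` passes
hand-marked boundaries through unchanged. The automated detector, needed
to run phantom experiments at scale, works on the column-averaged A-scan:

1. the anterior-RPE boundary is the strongest rising intensity edge — the
   RPE is the hyperreflective melanin-rich band, so its rising edge
   dominates the gradient;
2. the corneal apex is the first rising edge exceeding 40% of that
   maximum;
3. the four interior boundaries are located as the gradient extrema
   nearest a prior layout expressed as cumulative optical *fractions* of
   the apex-to-RPE span (defaults from `eye_phantom_spec()`), each inside
   a window of half the distance to its neighbouring boundaries.

Localizing on fractions of the detected span makes the detector invariant
to uniform eye growth, which is exactly the mutant-versus-wild-type
contrast of interest. Sub-pixel localization uses the centroid of the
above-half-maximum gradient magnitude, which is exact for symmetric steps.
The detector assumes the rendered contrast ordering (background < aqueous
< lens < cornea < retina < RPE); images violating it should use the
manual path.

## Eccentric photorefraction

Defocus shows up as a brightness gradient across the pupil under eccentric
infrared illumination. The measurement chain is: least-squares slope of
brightness versus pupil position (`estimate_slope()`); calibration by
trial lenses, regressing lens power on mean slope so the regression slope
*is* the conversion factor in D per slope unit (`calibrate()`); refraction
= conversion factor × mean slope over replicates (100 per eye in the
standard protocol, `average_refraction()`). Relative refraction subtracts
the mean wild-type refraction, removing the shared hyperopic offset of the
small-eye retinoscopic artifact; no explicit artifact correction model is
attempted.

**Profile phenotypes.** `classify_profile()` normalizes position and
brightness to [0, 1] so thresholds are unit-free, then compares a global
line with the best two-segment piecewise fit (breakpoint scanned over
interior samples, ≥ 3 points per segment). Defaults: a bifocal call needs
opposite-signed segment slopes and a ≥ 50% residual-sum-of-squares
reduction; an absent call needs a normalized global slope magnitude below
0.05 without such a split. Both thresholds are configurable; no published
numeric criterion exists for either, so these are package defaults chosen
to separate the three noiseless archetypes cleanly. On noise-only
profiles the normalized slope has sampling scatter (~0.1 SD at 50
samples), so "absent" is a statistical, not per-trace-certain, call at
realistic replicate counts — one reason the instrument protocol averages
100 replicates.

## Lens opacity and cataract

`opacity_ratio()` thresholds lens pixels with the classical
between-class-variance-maximizing (bimodal histogram) criterion — the de
facto default for this binarization — restricted to the lens mask, and
reports the fraction above threshold. Two guards handle degenerate
inputs: a constant lens reports ratio 0 with a flag, and a *bimodality
guard* requires the two class means to be separated by at least 3 pooled
within-class standard deviations. The guard matters because the criterion
always produces a split: on a unimodal noise histogram it cuts at the
mean and would label half of a clear lens opaque, while the separation of
genuinely opacified fibers is many times the noise scale.

`detect_nuclear_ring()` operationalizes "nuclear ring structure clearly
visible": the radial mean-intensity profile about the lens centroid is
compared with a running-median local baseline (window 15 radial bins),
and the ring score is the maximum over interior radius fractions
(0.1–0.8) of

$$\frac{\text{profile} - \text{baseline}}
       {\text{baseline} - \text{background}},$$

with the surround background median as the reference level. Both
numerator and denominator are intensity differences, so the score — and
hence the cataract call — is invariant to global affine
brightness/contrast transforms. The default call threshold is 0.10; it
has no published value and is configurable. Prevalences are rounded
half-up to integer percent; group contrasts are reported as
percentage-point differences of prevalence (a relative-increase reading
of such contrasts is arithmetic the caller can do on the same outputs).

## Optokinetic response

`detect_fast_phases()` computes central-difference angular velocity and
flags samples exceeding `velocity_factor` (default 3) times the drum
speed *against* the tracking direction; contiguous flagged samples form
saccadic reset events, and unflagged runs of ≥ 3 frames form slow-phase
intervals with least-squares velocities. The factor-of-3 criterion is a
package default validated against generator ground truth — resets in the
sawtooth model move two orders of magnitude faster than the drum, so the
detector is insensitive to the exact factor.

Gain is the median slow-phase velocity over the drum velocity (median
for robustness to residual saccade contamination; the mean is available).
A response at one spatial frequency is positive when ≥ 3 consecutive
cycles occur in both stimulus directions; "consecutive" means inter-reset
gaps ≤ 2 s. The 2 s default accommodates physiological reset rates of
roughly 0.5–2 per second — a 1 s cut-off would reject perfectly regular
nystagmus at 0.8 resets/s. The acuity staircase ascends from 0.15 cpd in
0.05 cpd steps; acuity is the highest positive frequency, with the
terminating negative frequency required twice for a verified run.

## Electroretinogram

Baseline correction subtracts the mean over the 50 ms immediately before
the *first* stimulus (recomputing per stimulus is available via
re-correction of epochs, but a single pre-train baseline is the default
because the inter-stimulus interval is long and drift-free in the
modelled protocol). Epochs aligned at each onset — two stimuli, 8000 ms
apart, in the standard protocol — are averaged point-wise, and the B-wave
amplitude is the maximum of the averaged corrected response within a
0–500 ms post-onset search window (the biphasic response template decays
well within it). Amplitudes can be normalized by body length (µV/mm).
The analog band-pass of the acquisition chain is treated as an
acquisition property; no digital filtering is applied by default. A-wave
metrics are not extracted.

## Cohort statistics

Because the two eyes of a fish are correlated, group contrasts use the
random-intercept linear mixed model
$y_{ij} = \beta_0 + \beta_1 \,\text{I(mutant)}_i + u_i +
\varepsilon_{ij}$, $u_i \sim N(0, \sigma_u^2)$, fitted by REML (standard
for small-sample variance components; `lme4` under the hood). Genotype is
the only fixed factor and eyes are exchangeable — no eye-side effect.
β₁ is reported with a Wald p-value on the normal reference. Body size is
handled by design, not covariance: `size_match_controls()` keeps
wild-type fish within ±10% of the mean mutant body length, whole fish at
a time, before fitting; body length is not additionally entered as a
covariate. Ages are analyzed cross-sectionally (fish are not individually
labelled across time points), and no multiple-testing correction is
applied across outcomes or ages; a Bonferroni adjustment is a caller-side
one-liner on the reported p-values. Welch's ANOVA
(`stats::oneway.test`, unequal variances) covers the unpaired functional
outcomes; for two groups it equals the square of Welch's t, which the
test suite checks against the textbook formula.

## What the generators emulate — and what they do not

The synthetic module produces every input with recorded ground truth;
designed quantities (slopes, gain, B-amplitude, opaque fraction, effect
size) are stored in the returned objects, never re-derived from pixels.

- **B-scan phantoms**: piecewise-constant reflectivity bands whose pixel
  extents encode thickness × index, with multiplicative Gaussian speckle
  (5% default in recovery experiments) — the simplest noise model of the
  right class. Real OCT speckle is correlated and non-Gaussian; real
  boundaries are curved and the lens has internal texture. Passing tests
  show the optical-path arithmetic and edge localization are right, not
  that the detector handles arbitrary clinical image quality.
- **Pupil profiles**: exact lines (or two opposite-signed half-lines for
  bifocal lenses) plus Gaussian noise on a normalized pupil coordinate.
  The optics producing the gradient are not simulated.
- **OKR traces**: ideal sawtooths — linear slow phases at gain × drum
  velocity, single-frame resets snapped to the frame grid (so designed
  slopes are exact), additive angular noise. No smooth pursuit, vergence,
  or blink artifacts.
- **ERG traces**: difference-of-gamma biphasic template (negative lobe
  peaking at 15 ms, positive at 40 ms by default), rescaled so the
  noiseless baseline-corrected maximum equals the designed B-wave
  amplitude exactly on the sample grid; the A-amplitude field is
  therefore a pre-scale shape parameter. White Gaussian noise only.
- **Lens images**: disk plus concentric rings; when a target opaque
  fraction is requested the ring width is solved on the pixel grid and
  the reported ground truth is measured from the *rendered* mask, keeping
  oracles exact under quantization.
- **Cohorts**: exactly the mixed model above, so effect recovery is a
  well-posed parameter-recovery experiment. Real cohorts have unequal eye
  counts, outliers, and age-varying variances.

All generators are pure functions of (spec, seed).

## Problem sizes and numerical choices

Recovery experiments run at desk scale: 200 simulated cohorts of 20 fish
per group for mixed-model recovery; 24-eye and 40-eye lens sets for
prevalence designs; 24 + 24 speckled phantoms (64 A-scan columns) for the
axial-length contrast; 30 s traces at 96 frames/s
for gain. These sizes bound Monte-Carlo error well below the contrasts of
interest while keeping the whole suite in the tens of seconds.

Tie-breaks and degenerate inputs are handled explicitly: sub-pixel
phantom compartments are rejected; saccade rates leaving no ≥ 2-frame
slow phase are rejected; inter-stimulus intervals shorter than the
response template are rejected; infeasible target opaque fractions are
rejected; constant images yield flagged zero ratios; a fully noiseless
cohort is degenerate for REML (zero residual variance) and is the one
place the test suite adds negligible (1e-8) jitter.

## Known limitations

Single-column or column-averaged axial segmentation only (no 3-D globe
reconstruction or en-face registration); no physical-optics simulation of
photorefraction, so absolute refraction inherits the calibration rig's
validity; ring detection assumes approximately disk-shaped lens masks and
concentric opacities; the OKR detector assumes uniform sampling; p-values
for the mixed model use the normal reference, which is mildly liberal at
very small fish counts.
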