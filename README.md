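# zfocular

Quantitative ocular phenotyping of zebrafish eyes in R.

Zebrafish are an increasingly popular model for refractive-error genetics:
their eyes grow fast, both eyes of a fish can be measured, and mutants can
be phenotyped with the same modalities used in the clinic. This package
implements the computational side of such a phenotyping battery as one
tested pipeline:

- **OCT biometry** — segment the six axial boundaries of a spectral-domain
  OCT B-scan (corneal apex → anterior retinal pigment epithelium) and
  convert optical path lengths to physical dimensions with tissue-specific
  refractive indices (cornea 1.33, aqueous/vitreous 1.34, lens 1.4, retina
  1.38): for each compartment, physical thickness = optical path / *n*, and
  axial length = Σ thicknesses.
- **Eccentric photorefraction** — estimate the slope *s* of the pupil
  brightness gradient by least squares, calibrate diopters per slope unit
  with trial lenses (power regressed on slope), convert RE = *k* · mean(*s*)
  over replicates, express mutant refraction relative to the wild-type
  baseline, and classify profiles as monofocal / bifocal / absent.
- **Lens opacity** — binarize coronal lens sections with a
  between-class-variance (bimodal histogram) threshold restricted to the
  lens mask, report the opaque-pixel ratio, detect nuclear ring opacities
  from radial intensity profiles, and compute cataract prevalences and
  percent transmission loss.
- **Optokinetic response (OKR)** — segment sawtooth nystagmus traces into
  slow and fast phases, fit per-interval slow-phase velocity, compute gain
  = eye velocity / drum velocity, count eye-tracking movements per 10-s
  interval, and evaluate the ascending spatial-frequency acuity staircase
  (0.15 cpd start, 0.05 cpd steps).
- **ERG** — baseline-correct voltage traces over the 50 ms pre-stimulus
  window, average the per-stimulus epochs, extract the maximal B-wave
  amplitude, and normalize by body length.
- **Cohort statistics** — size-match wild-type controls to within 10% of
  the mean mutant body length, then fit the paired-eye random-intercept
  linear mixed model
  *y*ᵢⱼ = β₀ + β₁·I(mutant) + *u*ᵢ + εᵢⱼ, *u*ᵢ ~ N(0, σ²ᵤ),
  by REML (genotype fixed, fish random), cross-sectionally per age;
  Welch's heteroscedastic ANOVA covers the unpaired functional outcomes.

Every input the pipeline consumes can be simulated with known ground truth
(`generate_bscan()`, `generate_pupil_profile()`, `generate_okr_trace()`,
`generate_erg_trace()`, `generate_lens_image()`, `generate_cohort()`), so
each stage is validated by parameter recovery.

## Worked example

Segment a speckled synthetic B-scan and recover its biometry:

```r
library(zfocular)
b   <- generate_bscan(eye_phantom_spec(noise = 0.05, seed = 7))
bio <- compute_biometry(segment_axial_boundaries(b))
bio$table
#>       compartment gap_px optical_um index physical_um
#>            cornea     13         26  1.33       19.55
#>  anterior_chamber      3          6  1.34        4.48
#>              lens    346        692  1.40      494.29
#>  vitreous_chamber    201        402  1.34      300.00
#>            retina    124        248  1.38      179.71
bio$axial_length_um
#> [1] 998
```

The phantom was built with a 1000 µm axial length; the 2 µm recovery error
is optical-path pixel quantization. Each `physical_um` is the boundary gap
(`gap_px` × 2 µm pixel depth) divided by the tissue index.

Fit the paired-eye mixed model on a simulated cohort with a −47 µm
genotype effect (20 fish per group, 2 eyes each):

```r
co  <- generate_cohort(cohort_spec(n_per_group = 20, effect = -47, seed = 1))
fit <- fit_random_intercept_lmm(co)
c(effect = fit$effect, se = fit$se, p = fit$p_value)
#>  effect -51.8   se 5.1   p 1.1e-24
```

The fitted genotype effect (−51.8 ± 5.1 µm) recovers the simulated −47 µm
within one standard error; averaging over replicate cohorts centres on the
design value (see the acceptance script).

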