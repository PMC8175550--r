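Package: zfocular
Title: Ocular Phenotyping of Zebrafish Eyes from OCT, Photorefraction, OKR and ERG Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for quantitative ocular phenotyping of
    zebrafish. Converts spectral-domain OCT optical path lengths to physical
    compartment dimensions and axial length using tissue-specific refractive
    indices, calibrates eccentric photorefraction brightness-gradient slopes
    to diopters with trial lenses, quantifies lens opacity and nuclear
    cataract from coronal sections, extracts optokinetic-response gain and
    eye-tracking movement counts from nystagmus traces, measures
    electroretinogram B-wave amplitudes, and ties outcomes together with
    random-intercept linear mixed models that account for paired eyes.
    Includes synthetic phantom, trace, image and cohort generators with
    known ground truth so every stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    tiff,
    png,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
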