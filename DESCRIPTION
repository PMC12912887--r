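Package: chromatch
Title: Quantifying Colour Change and Background Matching Through a
    Receiver's Eyes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantifying physiological colour change in
    background-matching experiments as seen by an avian receiver.
    Converts photographs with in-image grey reflectance standards to
    calibrated reflectance, maps calibrated measurements to avian cone
    catches, computes luminance, hue, saturation and trichromatic
    colour-space coordinates, scores fish-versus-background
    discriminability with the receptor-noise-limited model (achromatic
    and chromatic just-noticeable differences), and fits the
    repeated-measures mixed models (population-by-time interaction,
    Tukey-adjusted time contrasts on the response scale, AIC model
    ranking) used to compare colour-change capacity between
    populations. A synthetic-data generator reproduces the statistical
    structure of such experiments (populations, backgrounds, repeated
    photographs per fish, covariates) so the whole pipeline is testable
    without real photographs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
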