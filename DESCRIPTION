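Package: hapticsway
Title: Modelling and Analysis of Postural Sway Under Altered Haptic Feedback Gain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of quiet standing while lightly
    gripping a robotic object whose motion is coupled to body sway at a
    programmable gain. Implements a closed-loop stance model (linearised
    inverted pendulum, delayed proportional-derivative controller, touch
    and space sensory channels, threshold-based sensory-conflict estimator,
    filtered process noise), the empirical sway-analysis pipeline
    (zero-phase filtering and differentiation, segment-averaged power
    spectra with band integration, triaxial force magnitude, unbiased
    normalised cross-correlation), repeated-measures ANOVA with Tukey
    pairwise comparisons, 1/f-weighted spectral fitting of the model's
    noise and threshold parameters, and a synthetic-experiment generator
    emulating the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
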