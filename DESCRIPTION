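Package: fragsal
Title: Fragment Saliency and Fast-Vision Psychophysics Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying fast discrimination of fragment-occluded
    binarized images. Implements constrained maximum-entropy selection of
    information-optimal 3x3 binary features from image pattern statistics,
    generation of fragment-occluded two-interval forced-choice (2IFC)
    stimuli under explicit eccentricity, spacing and side-quota rules,
    per-fragment saliency (optimal-feature SNR) and Weber contrast metrics,
    and binomial mixed-model analyses linking saliency to discrimination
    performance. A synthetic-data module generates binarized power-law
    noise images with naturalistic 3x3 pattern statistics and simulates
    observer responses from an explicit logistic generative model, so the
    full pipeline is testable end to end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
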