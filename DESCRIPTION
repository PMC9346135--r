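Package: choroidref
Title: Nulla-Anchored Choroidal Morphometry for Segmented OCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic analysis pipeline for macular optical coherence
    tomography (OCT) volume scans that have been segmented into vitreous,
    retina and choroid compartments. Extracts layer boundaries from label
    masks, smooths the internal limiting membrane with a two-dimensional
    moving average, locates the deepest foveolar point (the "nulla") with
    center-of-mass tie handling, and measures a nulla-anchored grid of nine
    choroidal thicknesses (500 um steps out to +/- 2000 um), eight
    inter-landmark cross-sectional areas, and an umbo sub-analysis at
    +/- 100 um. Includes a synthetic OCT-segmentation generator with
    analytically known ground truth, a cohort statistics layer (subgroup
    summaries, coefficient of variation, Pearson correlation, two-way
    type-II ANOVA with Bonferroni banding), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    car,
    EBImage,
    dplyr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
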