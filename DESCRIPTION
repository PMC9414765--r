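Package: moldseed
Title: Hyperspectral Classification of Moldy Seeds with a Sparrow-Search-Tuned Random Forest
Version: 0.1.0
Authors@R: person("Maintainer", "Moldseed", email = "maintainer@moldseed.org", role = c("aut", "cre"))
Description: End-to-end pipeline for grading seed mildew severity from
    hyperspectral images: ENVI cube input/output and white/dark reflectance
    calibration, Otsu segmentation of seed plates with morphological cleanup
    and deterministic seed numbering, per-seed mean-spectrum extraction,
    chemometric preprocessing (standard normal variate, multiplicative
    scatter correction, Savitzky-Golay smoothing and derivatives),
    wavelength selection by random-forest impurity importance and by
    competitive adaptive reweighted sampling (CARS), and a sparrow search
    optimizer with an elite opposition (reverse) strategy that tunes the
    tree count and per-split feature-subset size of a random-forest
    classifier. Ships a ground-truthed synthetic-data generator emulating
    five ordered mildew-severity classes so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
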