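Package: actinmorph
Title: Morphometrics of the Actin Cytoskeleton from Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies actin cytoskeleton organisation from multi-channel
    fluorescence microscopy of fibroblasts. Implements reference-cell
    averaging of micropatterned cells (filtering, automatic thresholding,
    pattern centring, nucleus-based quality control, stack registration and
    0-255 frequency maps), filament and focal-adhesion morphometrics
    (skeleton-based length, width, orientation and position of single
    filaments; branch and junction counts; structure-tensor orientation
    distributions), proximity-ligation foci counting, line-scan peak
    frequency analysis of myosin puncta, wound-healing kinetics (closure
    percentage and migration rate), and the accompanying non-parametric
    group statistics (Kruskal-Wallis on replicate means with Dunn-Holm
    pairwise tests). A seeded synthetic-image generator with full ground
    truth supports validation of every detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
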