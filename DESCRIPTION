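Package: mpdascreen
Title: Multi-Parametric Analysis and Hit Calling for High-Content Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for image-based high-content compound screens
    run in 384-well plates: per-well aggregation of segmented object shape and
    fluorescence-intensity measurements into a 112-feature profile, Z'-factor
    based feature selection and plate quality control, Mahalanobis-distance
    scoring of every well against active- and negative-control models with
    shrunk covariance estimates, triage of dead and phenotypically disparate
    wells, duplicate-run hit calling with a 1-SD rule, dose-range hit
    validation, and target-class summaries. Includes a seeded synthetic screen
    generator (well images and fast feature-space tables) with ground truth so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
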