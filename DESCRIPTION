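Package: saxsdose
Title: Absorbed-Dose Simulation and Radiation-Damage Analysis for Solution SAXS
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative radiation-damage analysis of biological
    small-angle X-ray scattering (SAXS) experiments. Computes time-resolved
    absorbed dose for a static liquid sample in a cylindrical capillary
    (composition-derived X-ray absorption and attenuation coefficients,
    Beer-Lambert capillary wall transmission, measured or analytic 2-D beam
    profiles, per-frame diffraction-weighted dose). Assesses frame similarity
    with the CorMap longest-run test using exact Schilling p-values, detects
    damage onset via a three-consecutive-dissimilar-frames rule, ranks
    radioprotectant additives with the radiation damage onset threshold (RDOT)
    median-ratio metric, quantifies low-angle signal reduction, and renders
    correlation-map, reference-scatter and all-pairwise heat-map
    visualizations. Includes a seeded synthetic frame-series generator with
    known damage ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
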