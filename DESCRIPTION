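Package: fascicle
Title: Deterministic Multi-Peak Streamline Tractography and Bundle
    Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantitative analysis of white-matter
    fiber bundles from multi-peak fiber-orientation fields: deterministic
    generalized-streamline tracking with quantitative-anisotropy (QA)
    termination, geometric region-of-interest bundle extraction,
    dorsal/ventral subdivision from posterior termination morphology,
    streamline-count connectivity matrices with connection-index (CI)
    scaling, bundle volumetry with lateralization statistics, and
    CIRCOS-ready connectogram export. Includes a synthetic orientation-field
    phantom generator (curved tubes, posterior bifurcations, crossing
    bundles, hemispheric asymmetry) with analytic ground truth, plus
    packaged connection-index tables for an inferior longitudinal
    fasciculus (ILF) analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
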