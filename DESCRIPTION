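Package: sepxrf
Title: Seafood Elemental Profiling with Portable X-ray Fluorescence
Version: 0.1.0
Authors@R:
    person("Nadia", "Calder", email = "n.calder@example.org",
           role = c("aut", "cre"))
Description: Tools for developing and validating portable X-ray fluorescence
    (pXRF) soft-tissue elemental profiling protocols and for preliminary
    seafood provenance modelling. Includes instrument calibration via
    regression correction factors against a reference assay, protocol QC
    statistics (detection-inclusion rule, repeatability delta, exposure-time
    slope-improvement rule), paired nonparametric comparison of drying
    treatments, chemometric preprocessing (zero-fraction and correlation
    filters, z-scaling), supervised classification (random forest, linear
    discriminant analysis) and ordination (PCA, NMDS, canonical discriminant
    analysis), plus a synthetic-data generator that emulates the statistical
    structure of multi-element prawn profiles so the full pipeline is testable
    without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
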