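Package: refkin
Title: Reference-Region Kinetic Modeling and Simulation for Dynamic SV2A PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification workflow for dynamic brain PET with
    reversible radiotracers, built around synaptic density imaging with
    [18F]SynVesT-1. Constructs metabolite-corrected arterial input functions
    from automatic-sampler and manual blood data (plasma/whole-blood ratio,
    dispersion and delay correction, Hill parent-fraction fit), fits the
    one-tissue compartment model, the simplified reference tissue model
    (SRTM), its two-parameter SRTM2 variant with fixed or coupled reference
    efflux constant, and the Logan reference graphical method, and produces
    voxelwise SRTM2 parametric images by basis functions. Includes a
    synthetic-data generator for cohorts of ground-truth subjects, plus
    method-agreement, group-comparison, and scan-truncation (time-stability)
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
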