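Package: mucodiff
Title: Barrier Property Analysis for Native and Artificial Mucus
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis chain for characterising the diffusion barrier of
    mucus hydrogels and their synthetic mimics. Provides rheology-based
    theoretical mesh-size estimation from the storage modulus,
    fluorescence-recovery-after-photobleaching (FRAP) double normalization
    and circular-spot recovery fitting, multiple-particle-tracking
    mean-squared-displacement analysis with anomalous-diffusion-exponent
    fitting and transport-mode classification, cryo-SEM pore morphometry
    (fixed-threshold binarization, 8-connected labeling, Feret diameters
    by rotating calipers) with cross-validation against the rheological
    mesh size, and dissociation-constant estimation from microscale
    thermophoresis dilution series. Seeded synthetic-data generators
    emulate each instrument's output so the whole pipeline is testable
    without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
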