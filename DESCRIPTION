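Package: mcggtools
Title: Transport, Mixing and Dose-Response Analysis for Hydrogel
    Microfluidic Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for hydrogel-based microfluidic drug-screening
    devices fed by a tree-like microfluidic concentration gradient generator
    (MCGG). Implements the Stokes-Einstein transport chain (hydrodynamic
    radius, diffusivity, channel-crossing time), image-based mixing
    quantification (absolute mixing index, profile slope, end-of-mixer
    dilution estimation), a width-weighted dilution-network model with
    rectangular-duct hydraulic resistance, fluorescence correlation
    spectroscopy (FCS) triplet-model fitting with confocal-volume
    calibration, Fickian semi-infinite drug-penetration modelling, and
    Hill-type dose-response fitting with EC50 extraction. Seeded synthetic
    generators for mixing-channel micrographs, live/dead cell images, FCS
    autocorrelation curves and viability tables make every stage testable
    end-to-end with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
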