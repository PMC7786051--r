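Package: spherofall
Title: Spheroid Weight, Diameter and Mass Density from Free-Fall
    Sedimentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Flow-based videogravimetry for tumor spheroids. Tracks a single
    spheroid free-falling through a quiescent vertical channel in bright-field
    image sequences, fits its terminal velocity by per-repetition linear
    regression, and inverts buoyancy-corrected Stokes settling to recover mass
    density (fg/um^3), weight (ng) and diameter (um). Includes the
    multi-metric quality-control chain (Shapiro-Wilk normality screening,
    Tukey-fence outlier removal over terminal velocity, mass density, diameter
    and weight), cohort comparison by pooled two-sample t-tests with percent
    change, a synthetic falling-spheroid generator with known ground truth for
    validation, and a command-line pipeline (simulate, measure, qc, compare).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
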