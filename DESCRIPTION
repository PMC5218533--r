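Package: locokit
Title: Analysis of Fictive Locomotion, Hindlimb Kinematics, and Locomotor Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for locomotor neurophysiology: rectification
    and integration of ventral-root recordings, burst detection and
    double-normalized step-cycle segmentation, circular statistics on spike
    phases with a Rayleigh significance rule and spike subsampling,
    template-matching detection of postsynaptic currents with phase
    histograms, hindlimb gait kinematics including geometric two-link knee
    reconstruction and step-cycle normalization, and quantification of
    locomotor recovery after spinal transection via step ratios and
    Hill-curve fitting. Includes synthetic-data generators with full ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
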