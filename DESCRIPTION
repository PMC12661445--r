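Package: uncage
Title: Simulation and Analysis of Optically Actuated Calcium Release and
    Ultrasensitive Protein Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative microscopy assays in which a photocaged
    calcium chelator (DMNP-EDTA) is photolyzed inside a defined region of
    interest to actuate calcium-dependent self-assembly of an EF-hand protein
    (Tcb2), read out with the low-affinity fluorescent indicator Rhod-5N.
    Provides competitive binding equilibria, a reaction-diffusion forward
    simulator that renders fluorescence and brightfield image stacks with
    ground truth, indicator standard-curve calibration and inversion,
    spatiotemporal photobleaching correction, radial network-boundary
    tracking and outcome classification, dual-channel competition inference
    of calcium-bound protein, Hill-type ultrasensitivity fitting, phase
    portraits, and group comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
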