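Package: teloSPT
Title: Single-Molecule Tracking Analysis of Telomere-Binding Protein Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of single-particle tracking experiments
    on low-abundance nuclear proteins that exchange between free diffusion
    and chromatin binding, with a minority of binding events at telomere
    foci. Provides a ground-truth simulator of two-state diffusing molecules
    in a nuclear volume with an axial detection slice and photobleaching;
    Gaussian spot detection and gap-closing trajectory linking; a two-state
    (bound/free) jump-length-distribution fit with defocalization
    correction; distance-rule classification of tracks against telomere
    marker foci and the telomere-bound share of bound molecules;
    residence-time survival analysis with photobleaching correction; and
    absolute copy-number estimation from flow-cytometry mean fluorescence
    intensities with a reference standard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    tibble,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    tiff,
    EBImage,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
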