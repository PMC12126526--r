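Package: mouselift
Title: Buoyancy-Counterbalanced Head-Mounted Weight: Design Model and
    Behavioral/Calcium Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing helium-balloon counterweights for
    head-mounted neural imaging probes and for analysing their behavioral
    and neural consequences in freely-behaving mice. Includes a physical
    design model for balloon buoyancy, payload capacity and tether
    kinematics; open-field trajectory kinematics (path length, turning
    angle, velocity, acceleration) with velocity-threshold locomotion
    segmentation; a per-neuron fluorescence-rate statistic on delta-F/F
    calcium traces with a relative-threshold weight-sensitivity
    classification; random-intercept mixed-model inference with Bonferroni
    pairwise contrasts across experimental conditions; and a synthetic
    session generator (trajectories and calcium traces with planted
    condition effects) so every pipeline stage is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
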