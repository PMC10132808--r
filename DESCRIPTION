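Package: memtrack
Title: Single-Molecule Membrane Diffusion and Dwell-Time Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-particle tracking of membrane-bound
    proteins on supported lipid bilayers imaged by total internal reflection
    fluorescence (TIRF) microscopy. Simulates ground-truth-labeled Brownian
    trajectories with Markov state switching and exponential membrane
    desorption; links per-frame detections into trajectories with a linear
    assignment problem tracker with gap closing; builds step-size
    (jump-distance) distributions at multiple delay times with a
    non-overlapping skip rule and fits them globally to a multi-component
    two-dimensional diffusion mixture; fits exponential mixtures to membrane
    dwell times; and processes TIRF recruitment (adsorption) traces with
    baseline subtraction, replicate aggregation and washout comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    clue,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
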