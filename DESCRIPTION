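Package: flowstretch
Title: Single-Molecule Flow-Stretching and Pre-Steady-State Kinetic
    Analysis of DNA Polymerase Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of tethered-bead flow-stretching
    primer-extension experiments in which a fast replicative polymerase
    (Pol III) and a slow translesion polymerase (Pol IV) alternate on a
    primed single-stranded DNA template, together with pre-steady-state
    burst kinetic analysis (single-exponential burst fits, hyperbolic
    kobs-[dNTP] fits, catalytic efficiencies).  Includes a synthetic-data
    generator with full ground truth (trajectories, dark-field bead image
    stacks, kinetic time courses), worm-like-chain/freely-jointed-chain
    calibration of bead displacement to nucleotides synthesized, sub-pixel
    2D Gaussian bead localization, penalized piecewise-linear changepoint
    segmentation of synthesis traces into processive events and pauses,
    rate-based polymerase classification, processivity statistics with
    bootstrap ratios, and exact Wilcoxon rank-sum comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
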