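Package: casite
Title: Screening of Divalent-Cation Binding Sites in Acid-Sensing Ion
    Channels from Trajectories and Voltage-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to identify candidate Ca2+/Mg2+-binding acidic residues
    of acid-sensing ion channels (ASICs) from particle coordinate time
    series, and to quantify divalent-cation modulation of ASIC pH
    dependence from two-electrode voltage-clamp peak-current tables.
    Implements a two-step ion/carboxylate contact screen (10 Angstrom
    pre-screen at coarse sampling, 6 Angstrom residency criterion at fine
    sampling, second-passage exclusion), residency and distance metrics
    per residue, Hill fits of activation and steady-state desensitization
    pH dependence, inhibition-curve and single-exponential kinetics fits,
    paired midpoint shifts and tau ratios, and group statistics
    (paired t, ANOVA with Dunnett or Tukey contrasts). Includes synthetic
    generators with known ground truth: overdamped Langevin ion dynamics
    in planted Gaussian wells, per-oocyte peak-series simulation, and a
    three-state (closed/open/desensitized) gating model with proton-Ca2+
    competition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    minpack.lm,
    multcomp,
    deSolve,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
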