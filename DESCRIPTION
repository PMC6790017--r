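Package: archfatigue
Title: Cyclic-Loading Fatigue Analysis of the Medial Longitudinal Foot Arch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cadaveric cyclic-loading experiments on the
    foot arch: segments multi-channel load/displacement traces into loading
    cycles, computes the bony arch index (BAI = navicular height / foot
    length), arch flexibility and per-cycle energy absorption, fits polynomial
    creep trajectories with AIC-based order selection to locate the
    stage-II-to-III fatigue inflection point, and runs the nonparametric
    group-comparison battery (Kolmogorov-Smirnov screening, Kruskal-Wallis
    with Bonferroni-adjusted pairwise rank-sum tests, Friedman trend tests).
    Includes a calibrated synthetic-cohort generator emulating a three-group
    cadaveric experiment (normal 500 N, obese 1000 N, insole 1000 N; 10,000
    cycles at 1 Hz sampled at 20 Hz) so every stage is verifiable without
    access to original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
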