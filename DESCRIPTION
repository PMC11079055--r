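Package: titrascape
Title: Protonation Titration and Conformational Landscape Analysis for
    pH-Sensitive Ion Channels
Version: 0.1.0
Authors@R:
    person("Nina", "Aldrich", email = "nina.aldrich@posteo.net",
           role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for studying how protonation
    drives conformational change in pH-sensitive potassium channels.
    Implements an iterative self-consistent protonation-state protocol
    with a pluggable per-site pKa backend and an exact microstate
    enumeration oracle, per-frame trajectory geometry metrics (principal
    axis, residue orientation angle, side-chain centre-of-mass
    distances, channel-length proxy), smoothed two-dimensional
    distance-occurrence landscapes with region detection, replicate
    level Welch and ANOVA statistics, and a synthetic trajectory
    generator with hidden-Markov conformational switching that stands in
    for microsecond-scale molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
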