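Package: beesocial
Title: Social-State Detection and Spike-Rate Analysis for a Freely Behaving Honeybee
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating single-unit spike activity of a mushroom-body
    extrinsic neuron to the self-initiated social behavior of a freely moving
    honeybee inside an observation hive. The package reads multi-animal
    tracking tables and sorted spike times, bins spikes onto the 100 ms
    behavioral clock, derives walking speed, nearest-bee distance and
    body-axis orientation covariates, classifies 4 s windows into social
    states (alone, random, walking onset, passive contact, active contact)
    from distance and movement rules, and computes perievent time histograms,
    pre-contact peak latencies, within-window spike-rate variance, and
    distance-resolved rate analyses with Wilcoxon rank-sum, Rayleigh and
    Bonferroni-corrected statistics. A synthetic colony and spike-train
    generator with planted, recoverable effects makes every stage testable by
    parameter recovery without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
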