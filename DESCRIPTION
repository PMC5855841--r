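Package: cavgate
Title: Simulation and Analysis of CaV2.1 Whole-Cell Calcium Currents
    under Hypoglycosylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse whole-cell voltage-clamp
    recordings of P/Q-type (CaV2.1) calcium channels expressed in
    HEK293-like cells, under experimental conditions that perturb
    N-linked glycosylation (tunicamycin treatment, removal of the
    alpha2delta-1 subunit, and the N283Q sequon mutation of the
    alpha1A subunit). Includes a Boltzmann-ohmic current model with
    per-condition gating presets, a seeded synthetic-recording
    generator for step I-V and 3 s inactivation protocols, peak-current
    and current-density analysis, nonlinear Boltzmann I-V fitting,
    single-exponential inactivation kinetics, a from-scratch
    implementation of the nonparametric statistical battery
    (Mann-Whitney U, Kruskal-Wallis with Dunn post hoc, pooled
    Student's t, Fisher exact), clinical stroke-like-episode cohort
    summarisation, and an N-glycosylation sequon (N-X-S/T) scanner
    for protein sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
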