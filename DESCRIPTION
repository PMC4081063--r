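Package: TBPbind
Title: Branched Cooperative Lattice Model of TBP-DNA Binding with FRET
    Observables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Equilibrium and kinetic modelling of TATA-binding protein (TBP)
    association with short DNA fragments treated as one-dimensional binding
    lattices with a single specific (TATA box) register, footprint exclusion
    and nearest-neighbour cooperativity. Maps bound configurations to FRET
    efficiencies and proximity ratios through a DNA bending geometry model,
    simulates diffusing-molecule photon bursts and their proximity-ratio
    histograms, simulates competitor-chase dissociation experiments with one-
    and two-phase exponential fitting, and models site-exposure competition
    between TBP and a nucleosome covering the TATA box at the entry-exit
    site. Includes a seeded synthetic-data generator for titrations, chase
    traces and burst streams, and single-site isotherm fitting with biphasic
    deviation detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    BiocGenerics,
    Biostrings,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
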