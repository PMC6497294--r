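Package: ncstreams
Title: Emergent Neural Crest Stream Formation by Cellular Potts Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-dimensional cellular Potts model of cranial neural crest
    (NC) and epibranchial placode tissue interactions. NC cells chase placodes
    up an Sdf1 gradient, co-attract each other via a secreted factor, and both
    tissues repolarize away from heterotypic contacts (contact inhibition of
    locomotion), producing emergent migratory streams without any pre-pattern
    of guidance cues. The package provides the Monte Carlo lattice engine with
    a compiled inner loop, explicit reaction-diffusion solvers for the
    co-attractant, Sdf1 and inhibitor fields, per-cell polarity / CIL /
    persistent-adhesion dynamics with dorsal EMT insertion of new NC cells,
    pair-correlation morphometrics (stream width, length and counts), scenario
    presets, parameter sweeps and morphology maps, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    tools,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
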