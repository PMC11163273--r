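Package: condevol
Title: Coarse-Grained Simulation and Evolutionary Design of Multiphasic
    Protein-RNA Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue- and nucleotide-resolution coarse-grained modelling of
    liquid-liquid phase separation in protein-RNA mixtures. Implements a
    Mpipi-style interaction model (harmonic bonds, Wang-Frenkel short-range
    pairs, Debye-Hueckel screened electrostatics), direct-coexistence
    Langevin dynamics in slab geometry with cell-list acceleration, axial
    density-profile and multiphasicity analysis, and a genetic algorithm
    that evolves protein sequences toward increased or decreased
    multiphasicity of the condensate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
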