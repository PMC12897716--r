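Package: dpdgel
Title: Dissipative Particle Dynamics of Thermosensitive Polymer Nanogels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained simulation toolkit for the volume phase
    transition of thermosensitive (PNIPAM-like) polymer nanogels in water.
    Builds temperature-dependent dissipative particle dynamics (DPD) force
    fields from a Flory-Huggins interaction parameter using a
    parameterization that admits beads of unequal volume, constructs
    diamond-topology crosslinked nanogel networks, integrates the DPD
    equations of motion with a compiled velocity-Verlet engine (plus an
    implicit-solvent Langevin comparison mode), and analyses trajectories
    for the radius of gyration with block-averaged uncertainties, radial
    distribution functions, swelling ratios and the transition temperature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
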