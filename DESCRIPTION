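Package: memdeform
Title: Continuum Elastic Modelling of Bilayer Thickness Perturbation by Membrane Inclusions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing how membrane-deforming inclusions (amphipathic
    peptides, transmembrane peptides, and monolayer lipid patches) alter the
    average thickness of a lipid bilayer. Implements the linearized
    splay-tilt-compression elastic energy of a bilayer with monolayer-resolved
    neutral surfaces and director fields, minimizes it by finite elements on
    axisymmetric and planar domains, computes the single-inclusion thickness
    disturbance and its linear-response coefficients, and solves the inverse
    problem of recovering inclusion boundary parameters from average-thickness
    versus concentration data. Includes a synthetic thickness-series generator,
    an independent finite-difference oracle solver, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
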