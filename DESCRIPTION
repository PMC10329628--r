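Package: attachnet
Title: Patient-Specific Estimation of Organ Attachment Regions from Deformed Partial Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the Dirichlet attachment region (boundary
    conditions) of a deformable organ from partial views of its deformed
    surface. The package couples a Neo-Hookean hexahedral finite-element
    simulator, built on a regular-grid embedding of a closed organ surface,
    with a volumetric 3D U-shaped convolutional network that maps distance
    fields of deformed visible surfaces to a per-voxel attachment mask.
    Training data are generated synthetically from the patient geometry by
    sampling random attachment regions, random surface loads and partial
    camera views, and filtering out numerically unstable deformations.
    Includes a procedural generator of liver-like surfaces, registration
    based validation with nodal target errors, Dice overlap metrics and the
    associated non-parametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    nortest,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
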