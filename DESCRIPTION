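Package: beadstress
Title: Cell-Scale Stress Inference from Deformed Elastic Hydrogel Microbeads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the full Cauchy stress state inside a compressible
    elastic polyacrylamide microbead from its observed deformed
    three-dimensional shape, assuming a spherical stress-free reference
    configuration and a compressible Neo-Hookean material. Provides a
    geometrically nonlinear tetrahedral finite-element solver with follower
    pressure loads, a three-step inverse reconstruction pipeline (deformed
    mesh from confocal stacks, spherical reference construction via radial
    distance vectors, main stress-recovery solve), volumetric stress
    summaries and normal-stress--angle profiles, forward virtual load
    scenarios for validation, a synthetic confocal-stack generator with
    segmentation and volume estimation, and utilities relating osmotic
    bulk-modulus measurements to elastic moduli.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
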