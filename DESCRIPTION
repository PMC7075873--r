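Package: MreBTwist
Title: Coarse-Grained Mechanics of Twisted Membrane-Bound MreB Filaments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the interplay between intrinsic twist, membrane binding
    and length of bacterial actin (MreB) double protofilaments. Provides the
    elastic Hamiltonian of a chiral filament bound to the inner surface of a
    rigid cylinder, its analytical flat-membrane boundary-layer solution,
    Metropolis Monte Carlo energy minimization on curved membranes, and the
    resulting energy-length curves and limit lengths. Companion tooling turns
    molecular-dynamics-style observables into model parameters (Euler
    bend/twist angles between subunits, subdomain opening and dihedral
    angles, buried solvent-accessible surface area, membrane patch
    curvature, Gaussian fits of equilibrium angle fluctuations), quantifies
    fluorescent filament patches on flattened cell surfaces (segmentation,
    length and pitch-angle distributions), and generates seeded synthetic
    inputs with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    EBImage,
    bio3d,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
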