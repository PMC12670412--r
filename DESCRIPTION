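Package: slitwater
Title: Dynamics and Structure of Water Confined in Slit Pores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trajectory analysis for water confined between two planar
    surfaces (slit pores). Estimates the effective confinement width L by
    jointly fitting the perpendicular mean-square displacement to the
    restricted-diffusion solution for reflecting walls, fits parallel
    self-diffusion coefficients via the Einstein relation, characterizes
    reorientational dynamics through P2 orientational autocorrelation
    functions with stretched-exponential (KWW) plus order-parameter fits,
    and computes bond-orientation distributions and mass/number density
    profiles across the slit. Includes exact Brownian and rotational
    diffusion generators (reflected slit Brownian motion, isotropic and
    wobbling-in-a-cone rotors) providing ground truth for validation, plus
    readers for GROMACS GRO structures and a portable columnar trajectory
    format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'confinement.R'
    'msd.R'
    'pipeline.R'
    'reorientation.R'
    'slitwater-package.R'
    'structure.R'
    'synthetic.R'
    'trajectory-io.R'
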