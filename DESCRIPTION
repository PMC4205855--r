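Package: cumarea
Title: Cumulative-Area Analysis of Single-Molecule Diffusion and
    Conformational Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates lateral diffusion coefficients of single fluorescent
    particles from time-lapse image stacks by tracking the growth of the
    cumulative pixel area the molecule occupies, rather than by localizing
    its centre.  The cumulative-area (CA) estimator D = <dA>/(4*dt) uses
    forward and backward frame superimposition to recover area increments
    masked by previously visited pixels.  Includes per-frame background
    thresholding and footprint selection, stack quality gating, a
    single-molecule localization and tracking (SMLT) MSD baseline with 2D
    Gaussian localization, occupied-area autocorrelation analysis for
    conformational relaxation times of flexible polymers such as DNA, a
    2D random-walk simulator (Brownian, directed, confined; fixed, random
    and split pixel footprints) for validation, and population statistics
    over many molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
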