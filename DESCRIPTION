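Package: psigeom
Title: Geometry and Serial-Crystallography Analysis of Room-Temperature
    Photosystem I Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for comparing room-temperature and cryogenic
    crystal structures of large membrane pigment-protein complexes, built
    around Photosystem I. Implements anisotropic expansion analysis of the
    chlorophyll lattice in a P700-FX cylindrical frame, pi-stacking geometry
    of the phylloquinone binding pockets, perturbation-based coordinate
    precision estimation over model ensembles, and the serial femtosecond
    crystallography utilities needed upstream: coset-decomposition reindexing
    operators, tranche-based resolution of the merohedral indexing ambiguity,
    half-dataset CC1/2 resolution cutoffs, and unit-cell isoform
    classification by Gaussian mixtures. Ships seeded synthetic-data
    generators so every pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
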