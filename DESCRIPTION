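Package: carospec
Title: Conformation-Resolved Absorption Modelling for Protein-Bound Carotenoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale spectral analysis for carotenoid-binding proteins such
    as the helical carotenoid protein HCP2. Extracts end-ring (beta1/beta2)
    torsions of a carotenoid ligand from PDB structures, calibrates a
    conjugation-length surrogate surface mapping ring torsions and environment
    to the absorption maximum, builds and diagonalizes Frenkel exciton
    Hamiltonians for coupled chromophore assemblies (including point-dipole
    couplings from transition-dipole geometry), synthesizes Gaussian-broadened
    absorption spectra, decomposes spectral shifts into mechanistic stages, and
    summarizes snapshot ensembles with t-based confidence intervals and
    circular statistics. A seeded synthetic-data generator (von Mises dihedral
    mixtures, Gaussian snapshot ensembles, idealized stacked polyene dimers)
    makes every stage testable without quantum-chemistry or molecular-dynamics
    engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
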