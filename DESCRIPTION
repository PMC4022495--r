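Package: swapbp
Title: Structural Analysis of Domain-Swapped Substrate-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative structural analysis of bilobed periplasmic
    substrate-binding proteins (SBPs) that dimerize by three-dimensional
    domain swapping of their C-terminal helix, modelled on the
    thermostable arginine-binding protein of Thermotoga maritima
    (TmArgBP).  Provides rigid-body superposition and RMSD, Venus
    fly-trap closure-angle analysis between open (apo) and closed
    (ligand-bound) conformers, Shrake-Rupley solvent-accessible surface
    area and buried interface area, a census of salt bridges, hydrogen
    bonds and hydrophobic contacts with classification into the closed
    (C-) and open (O-) interfaces of a swapped dimer, backbone
    stereochemistry statistics (peptide planarity, N-CA-C angle,
    carbonyl pyramidalization as a function of psi), sequence-derived
    thermostability metrics, a one-set-of-sites isothermal titration
    calorimetry model with simulation and fitting, and deterministic
    synthetic-structure generators so the whole pipeline is testable
    without downloading deposited coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
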