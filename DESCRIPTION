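Package: ciufold
Title: Collision-Induced Unfolding Analysis for Traveling-Wave Ion Mobility
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("ciufold", "developers", email = "ciufold@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for collision-induced unfolding (CIU)
    experiments on native protein ions measured by traveling-wave ion
    mobility mass spectrometry (TWIMS). Converts arrival-time
    distributions to calibrated collision cross sections via the
    corrected power-law calibration, builds CIU fingerprints, fits
    four-parameter logistic unfolding curves to extract CIU50 and
    CIU_chi statistics with replicate ANOVA, models voltage-dependent
    ligand ejection, assigns protons to chargeable sites of a gas-phase
    protein ion by stochastic Coulomb-energy minimization, and computes
    projection-approximation collision cross sections and simple
    trajectory metrics (Kabsch RMSD, center-of-mass distances) from PDB
    structures. Ships a synthetic-data generator emulating a
    quadrupole/TWIMS CIU experiment on co-isolated apo, cofactor-bound
    and antibiotic-bound protein species, so the whole pipeline is
    testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
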