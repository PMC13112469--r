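Package: polybind
Title: Binding Free-Energy Decomposition for Poly(Gallic Acid)-Histidine
    Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale implicit-solvent binding analysis for complexes of
    enzymatically derived poly(gallic acid) with L-histidine. Provides a
    charged point-atom molecular model with PDB/PQR input and output, a
    synthetic-structure generator (idealized gallic-acid units, a helical
    oligomer, histidine in protonated and zwitterionic states, seeded
    rigid-body complex poses), a finite-difference Poisson solver for
    electrostatic solvation energies, pairwise Coulomb energies,
    Shrake-Rupley solvent-accessible surface areas with a gamma*dSASA
    non-polar term, pose scoring and ranking by binding free energy with
    hydrogen-bond interaction maps, and the accompanying assay arithmetic
    (probit IC50 estimation, linear calibration curves, ROS-inhibition
    percentages).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
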