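Package: hairpinfel
Title: Conformational Ensemble Analysis of Beta-Hairpin Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of beta-hairpin peptide conformational ensembles:
    sequence-based census of the non-covalent interactions that stabilize an
    antiparallel hairpin (register hydrogen bonds, facing hydrophobic pairs,
    central ionic pairs), structural descriptors (Kabsch superposition RMSD,
    radius of gyration, RMSF, Shrake-Rupley solvent-accessible surface area),
    DSSP-style secondary-structure assignment with Kabsch-Sander hydrogen-bond
    energies, per-bond register hydrogen-bond tracking, autocorrelation
    functions, and free-energy landscapes over (RMSD, Rg) by Boltzmann
    inversion with basin extraction. Ensembles are read from multi-model PDB
    files or generated by a built-in coarse-grained hairpin model sampled with
    replica-exchange Metropolis Monte Carlo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
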