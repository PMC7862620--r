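Package: plscore
Title: Physics-Based Empirical Scoring of Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("plscore", "developers", email = "plscore@example.org",
           role = c("aut", "cre"))
Description: Computes physics-based interaction descriptors for
    protein-ligand complexes (distance-dependent dielectric
    electrostatics, buffered 14-7 van der Waals, piecewise lipophilic
    contacts, solvent-accessible-surface based polar and nonpolar
    solvation, and a frozen-rotatable-bond torsional entropy count),
    applies published multiple-linear-regression scoring functions
    (general, protease-specific and protein-protein-interaction
    inhibitor specific coefficient sets), retrains linear, epsilon-SVR
    and random-forest models on descriptor tables with tenfold
    cross-validation, and evaluates affinity prediction and virtual
    screening with Pearson R, RMSE, ROC AUC, enrichment factors and
    BEDROC. Includes deterministic synthetic fixtures (toy complexes,
    planted-coefficient feature tables, screening score sets) so the
    whole pipeline is testable without external structure databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
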