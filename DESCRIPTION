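Package: cosmoscreen
Title: COSMO-SAC Phase Equilibria for Amorphous Solid Dispersion Screening
Version: 0.1.0
Authors@R:
    person("cosmoscreen", "developers", email = "cosmoscreen@example.org",
           role = c("aut", "cre"))
Description: Predictive screening of drug-polymer compatibility for amorphous
    solid dispersions with the COSMO-SAC activity-coefficient model. Parses
    Gaussian-dialect COSMO segment files, performs charge-density averaging
    and hydrogen-bond-class sigma-profile binning, builds virtual-macromolecule
    sigma-profiles by monomer-unit replication of oligomer data, and evaluates
    residual, Staverman-Guggenheim or free-volume combinatorial, and Margules
    dispersion contributions to ln(gamma). Solves solid-liquid equilibria for
    crystalline drug solubility, liquid-liquid equilibria (binodal and
    spinodal) for amorphous-amorphous phase separation, assembles phase
    diagrams with UCST/LCST detection, ranks polymer carriers, and computes
    deviation statistics against experimental solubility tables. Includes a
    command-line interface and deterministic synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
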