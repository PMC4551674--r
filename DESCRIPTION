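Package: rnagame
Title: Game-Theoretic Coarse-Grained Sampling of RNA 3D Structure Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Samples coarse-grained RNA 3D conformations on a face-centred
    cubic lattice by treating secondary-structure elements as players of a
    repeated game. Each player chooses lattice move directions with a
    regret-minimizing multi-armed bandit (UCB1 or EXP3) and is rewarded by
    knowledge-based pair potentials (Lennard-Jones, modified Lennard-Jones,
    Gaussian mixture, or inverse-square forms) fitted from inter-player
    distance distributions. Includes dot-bracket parsing and decomposition
    into helices and junctions, coarse-graining of native PDB structures,
    Kabsch superposition and RMSD evaluation of sample sets, and a
    synthetic-fixture generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    mclust,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
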