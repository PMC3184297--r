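Package: locoscore
Title: Local-Coordinate Knowledge-Based Scoring of Protein Main Chains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A coarse-grained knowledge-based potential for protein main-chain
    evaluation. Each residue anchors a right-handed local Cartesian frame on
    its N, C-alpha and C atoms; the C-alpha atoms of interaction partners are
    located in 1 Angstrom cubic bins of that frame and scored by inverse
    Boltzmann log-odds against a 400-pair mean reference state, with a
    zero-count penalty for bins never observed in training. The package
    provides the trainer (sparse count accumulation and database compilation),
    the scorer, a Kabsch C-alpha RMSD, the full decoy-set evaluation metric
    suite for native recognition and decoy discrimination, a paired one-tailed
    Wilcoxon comparison of scoring functions, an omega-angle baseline
    discriminator, parameter-grid cross-validation, a synthetic backbone and
    decoy generator for self-contained testing, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
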