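Package: ubikin
Title: Kinetic and Quantitative Analysis of SCF-Catalyzed Poly-Ubiquitylation Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form and stochastic models of single-encounter sequential
    poly-ubiquitylation chains, estimation of per-step ubiquitin-transfer rate
    constants from quench-flow densitometry time courses, Michaelis-Menten
    characterization and catalytic-efficiency comparison of chain-initiating
    and chain-elongating E2/E3 enzymes, conversion of SILAC spike-in selected
    reaction monitoring measurements into cellular enzyme concentrations, and
    differential scoring of genome-wide CRISPR knockout screens with sgRNA
    off-target mismatch scanning. Includes seeded synthetic-data generators
    emulating each experimental input so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
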