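Package: fluximba
Title: Flux Imbalance Analysis of Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction, validation and biological interpretation of
    shadow prices (the dual variables of the steady-state constraints)
    in constraint-based metabolic models. Solves the flux balance
    analysis primal and its explicit dual with a built-in
    bounded-variable simplex, reports shadow prices with their validity
    ranges, validates them against alternate optima by brute-force
    re-solves, classifies growth-limiting metabolites, simulates gene
    knockouts through Boolean gene-protein-reaction rules, integrates
    gene-expression data via an inconsistency-score linear program
    whose shadow prices predict metabolite accumulation or depletion,
    and links shadow prices to the temporal variability of metabolite
    pools with permutation tests and classifier statistics. Reads and
    writes models in SBML Level 3 (FBC), a JSON dialect, and a simple
    TSV dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
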