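Package: pldscreen
Title: Quantification and Prediction of Drug-Induced Phospholipidosis from
    Plate-Based Screens
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cell-culture phospholipidosis (PLD)
    screens: per-plate background subtraction and percent-of-control
    normalization of well fluorescence, activity calling at a doubling
    threshold, concentration-consistency and nuclear-stain (DAPI) quality
    control, cationic-amphiphilic-drug and Lipinski rule classifiers,
    likelihood-ratio and Fisher exact association tests on 2x2 contingency
    tables, ATC second-level enrichment tabulation, a beam-search descriptor
    subset selector fitted with a compact depth-bounded random forest and
    validated by out-of-bootstrap resampling, and an additivity analysis for
    drug combinations. A seeded synthetic-screen generator reproduces the
    statistical structure of a 297-compound quadruplicate screen so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ranger,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
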