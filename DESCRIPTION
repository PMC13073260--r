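Package: revnet
Title: Treatment-Reversal Screening and Network Module Integration for
    Three-Group Multi-Omics Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrated analysis of three-group
    (control / disease model / treated) multi-omics experiments.
    Implements per-feature differential screening with fold-change and
    p-value thresholds, orthogonal partial least squares discriminant
    analysis (OPLS-DA) with variable importance in projection (VIP)
    scores and permutation validation for metabolomics, identification
    of features whose disease-associated change is reversed by
    treatment, MCODE-style dense-module detection on an interactome,
    the shortest-path network-separation score S_AB for ranking
    gene-module/protein-module synergy, degree-based hub ranking, and
    hypergeometric over-representation analysis against user-supplied
    gene-set collections. A synthetic-data generator emulating the
    study design (three groups, planted perturbed and reversed
    features, modular interactomes) makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
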