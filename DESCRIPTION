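Package: tmcontact
Title: Inter-Helix Residue Contact and Helix-Helix Interaction Prediction
    for Alpha-Helical Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature-based random-forest prediction of inter-helix
    residue-residue contacts in alpha-helical transmembrane proteins, and
    inference of interacting helix pairs from the ranked contacts. Builds
    per-pair feature vectors from evolutionary profiles, correlated-mutation
    scores (MI, MIp, MIc, OMES, McBASC), positional conservation and helix
    geometry descriptors; supports correlation-based feature selection with
    best-first search, leave-one-protein-out evaluation (top L/5 accuracy,
    coverage, delta-analysis, chain-averaged precision-recall curves) and a
    synthetic helix-bundle generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    randomForest,
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
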