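Package: tatarget
Title: Physicochemical Prediction of Tail-Anchored Protein Targeting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the C-terminal targeting information of
    tail-anchored (TA) membrane proteins. Detects the C-terminal
    transmembrane domain (TMD) by a sliding-window Kyte-Doolittle scan,
    computes TMD hydrophobicity (GRAVY) and Henderson-Hasselbalch net tail
    charge, summarises and compares these features across organelle groups
    (peroxisome, mitochondrion, endoplasmic reticulum and shared), and
    trains a probabilistic radial-basis-function support vector machine
    that predicts the targeting organelle of an uncharacterised TA protein
    from its tail charge and TMD GRAVY. Includes a synthetic sequence and
    feature generator so every stage can be exercised without external
    downloads, plus a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
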