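Package: glysite
Title: Two-Stage Prediction of N-Linked Glycosylation Sites in Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts N-linked glycosylation sites at N-X-S/T sequons of
    protein sequences with a two-stage approach. The first stage scores whole
    proteins by a similarity-voting scheme over homology-search hit sets; the
    second stage classifies individual sequons with a radial-basis support
    vector machine built on gapped-dipeptide ratio features and pattern-based
    encodings of predicted surface accessibility and secondary structure.
    Final calls combine both stages through a score-adjustment rule. Includes
    deterministic synthetic-data generators for every input the pipeline
    consumes, full evaluation metrics (accuracy, precision, sensitivity,
    specificity, MCC, ROC/AUC), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
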