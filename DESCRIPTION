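Package: coevolink
Title: Inter-Protein Residue Coevolution Scanning with Filtered Mutual
    Information
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects coevolving residue pairs between two proteins from
    paired multiple sequence alignments of orthologs. Every cross-protein
    column pair is scored with mutual information after per-term frequency
    filters, scores are normalized by the comparison-wide average (times
    10,000), and the top normalized score is converted into a calibrated
    percent chance that the two proteins interact using embedded
    vertebrate and bacteria threshold tables. Includes the hyperparameter
    grid search and evaluation statistics used to tune the filters, the
    probability-table calibration machinery, a synthetic paired-alignment
    simulator with planted coevolving columns, output writers (summary
    TSV, detailed CSV, heatmap) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    grDevices,
    graphics,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
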