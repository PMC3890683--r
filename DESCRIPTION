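Package: barcodeID
Title: Feasibility Analysis of DNA Barcode Reference Libraries for
    Species Identification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate whether a COI barcode reference library can
    identify species reliably. Computes Kimura 2-parameter distances with
    pairwise deletion, intra/interspecific distance summaries and
    barcode-gap overlap, neighbour-joining trees with polytomy collapse and
    bootstrap supports, and five leave-one-out identification criteria:
    tree-based clustering (NJT), its node-level refinement (NJT_M), Best
    Match (BM), Best Close Match (BCM) and All Species Barcodes (ASB).
    Derives 95th-percentile and ad hoc distance thresholds, classifies
    queries into true/false positives and negatives with the associated
    accuracy, precision and identification-error metrics, runs
    dataset-stripping experiments, flags problematic taxa, and includes a
    hierarchical two-parameter sequence simulator so the whole pipeline can
    be exercised end to end on synthetic reference libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
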