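Package: barcodegap
Title: Evaluation of Candidate DNA Barcode Markers via Distance Gaps and
    Neighbor-Joining Trees
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing candidate DNA barcode regions from aligned
    multi-species sequence data: Kimura 2-parameter and p-distance matrices
    with pairwise deletion, partitioning of pairwise distances into intra- and
    inter-specific classes, per-species closest-neighbour summaries and
    barcoding-gap detection, distance histograms at configurable bin widths,
    neighbor-joining tree construction with Felsenstein bootstrap supports,
    outgroup rooting and per-species monophyly checks, per-marker
    amplification/sequencing success accounting, and a seeded sequence
    simulator under the Kimura 2-parameter substitution process with
    multi-species structure and per-sample dropout, so the whole pipeline can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
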