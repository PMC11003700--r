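Package: regquad
Title: Integrative ChIP-seq/RNA-seq Regulatory Classification and Drug
    Synergy Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying transcription-factor binding sites into
    promoter-like and enhancer-like chromatin states from multi-mark
    ChIP-seq signal, annotating peaks against a gene model, computing
    binned signal matrices and metagene profiles around peak centers,
    calling super-enhancers by rank-curve inflection, counting peak-set
    overlaps with min-linkage component semantics, integrating binding
    with differential expression into regulatory quadrants, binning
    between-condition occupancy changes, and scoring checkerboard
    drug-combination matrices under the Bliss independence model.
    Includes a synthetic-data generator with machine-readable ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
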