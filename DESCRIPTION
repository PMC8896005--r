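Package: TEmotifs
Title: Transcription Factor Binding Motifs in Transposable Elements
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of transcription-factor DNA-binding motifs
    inside transposable elements (TEs). Implements position-weight-matrix
    scanning against a zero-order Markov background with exact score-to-p-value
    dynamic programming, strict-containment assignment of motif hits to
    annotated TEs, per-(motif, TE-type) fold-enrichment statistics with a
    binomial null and the coverage/fold/p filter cascade, genomic feature
    partitioning and TE coverage tables, chromatin accessibility and
    TF-binding association from extended peak summits (including a Fisher's
    exact accessibility test), and a cross-species ortholog promoter-TE-sharing
    hypergeometric test. A seeded synthetic-genome generator with planted
    ground truth supports closed-loop validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
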