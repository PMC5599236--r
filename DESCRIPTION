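Package: TEmimic
Title: Discovery of Transposon-Derived miRNA Target Mimics in Plant
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for nominating transposable-element (TE)
    transcripts that act as competing endogenous RNAs (miRNA target mimics)
    in a plant transcriptome. Implements miRNA-target duplex expectation
    scoring with G:U wobble and seed-region weighting, transcript scanning
    and mimicry classification by the central (cleavage-register) mismatch
    rule, Smith-Waterman homology-patch detection between TE and gene
    transcripts in both orientations, binding-site-density enrichment with a
    first-principles Wilcoxon rank-sum test, RPKM normalisation and
    tissue-wise TE-gene co-expression pairing, degradome (PARE) cleavage
    calling with CleaveLand-style categories, and LTR retrotransposon
    insertion-age dating from LTR divergence. A synthetic-data module
    generates all pipeline inputs with known ground truth so every stage is
    testable end to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
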