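Package: miRPair
Title: Paired-Library Small RNA Sequencing Analysis of miRNA Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing microRNA expression between two small RNA
    sequencing libraries sequenced without biological replicates. Covers the
    full analysis chain: adapter trimming and quality filtering of raw reads,
    collapsing to unique tags, priority-based annotation against contaminant
    ncRNA references and a hairpin catalog with mismatch-tolerant matching,
    miRNA:miRNA* duplex detection, reads-per-million normalization, an exact
    conditional count test for two-library differential expression with
    fold-change based significance labelling, expression category reporting,
    and qPCR delta-Ct validation arithmetic. Includes a synthetic read
    simulator with known per-miRNA truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    yaml,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
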