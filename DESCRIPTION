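Package: mirseq
Title: Small RNA Sequencing Analysis and miRNA Discovery Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for plant small RNA sequencing analysis:
    read cleaning and adapter trimming, collapsing to unique tags, genome
    mapping and priority-based annotation into ncRNA/miRNA/exonic/intronic
    categories, known mature miRNA identification against a miRBase-style
    reference, novel miRNA hairpin precursor calling with an embedded
    nearest-neighbour RNA folding engine, TPM-normalised differential
    expression with the Audic-Claverie Poisson-model test, and rule-based
    plant miRNA target prediction with G:U wobble scoring. Includes a
    synthetic data generator that plants hairpin loci, contaminant ncRNA
    fragments and designed condition effects so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
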