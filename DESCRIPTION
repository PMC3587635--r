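Package: ssrmir
Title: Mining Simple Sequence Repeats and SSR-Bearing Pre-miRNA Candidates
    in Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for plant transcriptome unigenes: detects
    perfect simple sequence repeats (2-5 nt motifs, five or more iterations),
    folds 120-nt windows into minimum-free-energy secondary structures with a
    nearest-neighbour energy model, accepts pre-miRNA hairpin candidates under
    explicit stem-loop filtering criteria, predicts miRNA targets under plant
    complementarity rules, classifies SSR position relative to each candidate
    (upstream/within/downstream) with an exact binomial bias test, and computes
    RPKM expression classes. Includes a seeded synthetic-transcriptome
    generator with machine-readable truth tables for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
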