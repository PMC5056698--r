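Package: stripecre
Title: Identification of Ftz/Ftz-F1-Responsive Genes and Candidate
    Cis-Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing pair-rule-dependent
    cis-regulatory elements in the Drosophila blastoderm. Screens a staged
    wildtype-vs-mutant expression experiment (permutation ANOVA with
    q-value FDR and a signed fold-change filter cascade), intersects ChIP
    peak intervals with degenerate IUPAC consensus sites near responsive
    genes, builds order-k Markov background models of peak sequence,
    tests k-mer over-representation, scans JASPAR position weight
    matrices against an empirical Gaussian null, and compares confirmed
    against false enhancers by motif presence and chromatin-track
    overlap. Ships a seeded synthetic-data generator with planted signal
    so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
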