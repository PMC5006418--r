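Package: rnahomology
Title: Sensitivity-Tuned Homology Search and Annotation of Non-Coding RNAs
    in Fragmented Draft Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-strategy homology pipeline for annotating non-coding
    RNA genes (miRNAs, snRNAs, snoRNAs, rRNAs and others) in highly
    fragmented draft genome assemblies.  Combines word-seeded local
    alignment under an ensemble of sensitivity-tuned scoring schemes with
    Karlin-Altschul statistics, rule-based candidate filtering and
    merging, profile hidden Markov model scanning, and covariance-model
    (SCFG/CYK) cross-validation with gathering-score, E-value and
    model-coverage acceptance rules.  Includes bacterial contamination
    screening, shuffle-based null models for sensitivity/specificity
    estimation, Dollo-parsimony reconstruction of ncRNA family gain and
    loss on a species tree, and a synthetic-genome generator with planted
    homologs for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    phangorn
Config/testthat/edition: 3
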