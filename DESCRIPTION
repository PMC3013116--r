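Package: medresq
Title: Mutation Detection by Mediator-Genome Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies acquired mutations in a bacterial isolate that lacks a
    same-strain reference genome by sequencing both the mutant and its wild-type
    parent and mapping the short reads of each onto the genome of a related
    "mediator" organism. Differences against the mediator that recur in both
    isolates reflect evolutionary divergence and are discarded; differences
    unique to the mutant are candidate causative mutations. Provides a
    seed-and-extend short-read aligner with a bounded error model, pileup-based
    consensus variant calling with strict and relaxed thresholds, detection of
    uncovered and hyper-mutated regions, difference-table subtraction,
    codon-level effect annotation, direct-repeat detection at deletion
    breakpoints, and a synthetic-data generator with truth sets for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    IRanges,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
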