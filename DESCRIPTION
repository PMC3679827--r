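Package: hybridexpress
Title: Transcript Inheritance and Allelic Bias in F1 Interspecific Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for transcript-level inheritance in first
    generation (F1) interspecific hybrids from RNA-seq read counts.
    Implements median-of-ratios normalization, a negative-binomial exact
    test for pairwise differential transcript accumulation between two
    parental accessions and their F1 offspring, midparent (additivity)
    linear modelling with influence pruning and prediction bands,
    classification of transgressive and high-variance transcripts,
    discovery of fixed inter-parental SNPs from pileup tables, and
    detection of allelic bias within F1 individuals as evidence of cis
    regulatory divergence.  A negative-binomial synthetic-data generator
    with planted parental, cis, trans, transgressive and high-variance
    effects makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
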