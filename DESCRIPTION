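Package: divSplice
Title: Differential Transcript Usage from RTA-Divided Transcript Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical framework for differential transcript usage (DTU)
    analysis of RNA-seq transcript quantifications. Technical resamples
    (bootstrap or Gibbs draws) from quantifiers such as Salmon are used to
    estimate the quasi-Poisson overdispersion induced by read-to-transcript
    ambiguity (RTA); transcript counts divided by these overdispersions
    behave like negative binomial counts and are analysed with
    transcript-wise weighted linear models on log-CPM or quasi-negative
    binomial generalized linear models. Differential usage is tested within
    each gene by empirical Bayes moderated t- and F-statistics or by
    quasi-F statistics from deviance differences, with Simes aggregation to
    gene-level p-values. A count-level simulator with ground-truth
    bookkeeping and a benchmarking harness for type I error, FDR and power
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    jsonlite
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
biocViews: RNASeq, DifferentialSplicing, AlternativeSplicing,
    GeneExpression, Transcriptomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
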