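Package: dormscan
Title: Tumor Mass Dormancy Scoring and Mutational Process Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies tumor mass dormancy (TMD) and its immunological and
    angiogenic components from bulk expression data using gene-program
    scores (scaled difference of means, PCA, mean expression), classifies
    samples by quartile and proliferation/apoptosis rules, and links
    dormancy to tumor mutagenesis: 96-channel single-base-substitution
    catalogues, constrained signature refitting with explicit signature
    selection rules, de novo signature extraction with stability-based
    rank selection, APOBEC tCw enrichment, consensus clustering of
    signature exposures, driver-mutation enrichment statistics,
    microenvironment and hypoxia scoring, and survival analysis. Ships a
    fully synthetic multi-modal cohort generator with planted ground truth
    so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    survival,
    randomForest,
    mclust,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
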