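Package: methylAging
Title: Epigenetic Aging Analysis of 6mA and 5mC Methylomes from Modified-Base Pileups
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying DNA methylation aging signatures in
    N6-methyladenine (6mA) and 5-methylcytosine (5mC) methylomes called from
    long-read modified-base pileups (bedMethyl tables). Provides coverage
    filtering and multi-sample matrix assembly, differential methylation
    calling with Benjamini-Hochberg FDR control and genomic-context
    annotation, site- and sample-level methylation Shannon entropy, per-site
    rate-of-change regression, three penalized-regression epigenetic clocks
    (elastic net on methylation levels, ridge on differentially methylated
    sites, elastic net on site entropies) trained with nested leave-one-out
    cross-validation, permutation significance and feature-selection
    stability assessment, and detection of treatment-induced epigenetic age
    deceleration. Includes a synthetic aging-methylome cohort generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml,
    car,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Regression, Aging, Sequencing
RoxygenNote: 7.3.3
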