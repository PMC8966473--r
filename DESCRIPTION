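Package: parafreq
Title: Detecting Parallel Allele Frequency Change Across Replicate Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multivariate detection of convergent allele-frequency change across
    replicate population pairs. Builds windows of allele-frequency-change
    vectors between a source population and each derived population, performs
    eigenanalysis of the window correlation matrix C = XX', calls outlier
    windows against an individual-shuffling permutation null, forward-simulates
    neutral Wright-Fisher drift conditioned on census population sizes, and
    standardizes observed allele-frequency change as per-generation selection
    coefficients compared against neutral simulation quantiles. Includes a
    synthetic-genotype generator emulating a one-source, multiple-introduction
    study design, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
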