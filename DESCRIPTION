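Package: metwave
Title: Wave Clustering and Linear/Parallel Ratio Analysis of Metastasis
    Diameters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers the clonal trajectory of cancer metastases from their
    measured diameters. Metastases within a patient and organ are clustered
    into dispatch "waves" by a one-dimensional gap-threshold rule with an
    organ-specific tolerance, and the linear/parallel ratio (LPR) summarises
    how much of the burden is clusterable. Includes cohort summary tables
    (medians with interquartile ranges, group comparisons), Kaplan-Meier
    survival analysis from two time origins with a Gehan-Wilcoxon curve
    comparison, and a seeded generative simulator of linear versus parallel
    dissemination for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
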