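Package: genetest
Title: Gene-Based Association Tests over Shared Sufficient Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-level association testing for genome-wide SNP data.
    Implements six gene-based statistics -- greedy Bayesian model selection
    (GWiS), average single-SNP Bayes factors (BIMBAM), the sum of single-SNP
    chi-squares (VEGAS), the extended Simes procedure (GATES), and best-SNP
    tests with and without gene-size correction -- together with conventional
    single-SNP scans, all computed over shared per-gene sufficient statistics
    and a shared Fisher-Yates permutation stream.  Every test runs either on
    individual-level genotype dosages (fractional, imputation-ready) or on
    per-SNP summary statistics with linkage disequilibrium reconstructed
    on demand from a reference haplotype panel.  Includes a simulator for
    case-control and quantitative-trait study designs so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
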