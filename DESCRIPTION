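Package: ironmr
Title: Two-Sample Mendelian Randomization for Iron Status and Liver Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: reading and validating per-variant association tables,
    allele harmonization across exposure and outcome studies (including
    strand flips and palindromic variants), instrument selection by
    genome-wide significance, linkage-disequilibrium pruning and
    F-statistic grading, causal-effect estimation by Wald ratio,
    fixed-effect inverse-variance-weighted meta-analysis, MR-Egger
    regression and the bootstrap weighted-median estimator, analytic power
    approximation for continuous and binary outcomes, a summary-level
    simulator with configurable horizontal pleiotropy and known ground
    truth, and a study runner that evaluates an exposure-by-outcome grid
    (including sex strata and reverse analyses) and renders results tables.
License: MIT + file LICENSE
Encoding: UTF-8
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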