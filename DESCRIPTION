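Package: netmr
Title: Network Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-sample Mendelian randomization from GWAS summary statistics,
    organised around a network (mediation) framework: allele harmonization,
    instrument construction (p-value filtering, LD clumping, greedy
    variance-explained maximization under a Cochran's Q homogeneity
    constraint), inverse-variance-weighted and MR-Egger estimation,
    leave-one-out sensitivity analysis, three-step mediation with mediated
    proportions, bidirectional analyses, analytic power calculations for
    binary and continuous outcomes, and a synthetic summary-statistics
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
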