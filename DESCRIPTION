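Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) workflow for
    tabular GWAS summary statistics: instrument selection (p-value screening,
    greedy LD clumping, proxy search, exclusion lists), allele harmonization
    with the frequency-based palindromic-SNP rule, five causal estimators
    (inverse-variance weighted, MR-Egger, weighted median, weighted mode,
    simple mode), heterogeneity and pleiotropy diagnostics (Cochran's Q,
    Egger intercept, leave-one-out, forest and funnel tables), multivariable
    MR for direct effects, mRnd-style statistical power for binary outcomes,
    and a synthetic two-sample summary-data generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
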