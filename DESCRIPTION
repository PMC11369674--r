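Package: mrmediate
Title: Two-Sample, Multivariable and Two-Step Mediation Mendelian
    Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for causal inference with genetic instruments from GWAS
    summary statistics: reading and allele-harmonizing per-variant
    association tables, selecting and LD-clumping instruments with F-statistic
    strength filters, univariable two-sample estimators (Wald ratio,
    inverse-variance weighted, MR-Egger, weighted and simple median),
    heterogeneity and pleiotropy diagnostics (Cochran's Q, Egger intercept,
    leave-one-out), multivariable MR by weighted linear regression, and a
    two-step mediation decomposition (product of coefficients, proportion
    mediated, mediation-versus-masking classification) with delta-method and
    Monte-Carlo intervals. A structural-model simulator generates three-trait
    summary statistics with linkage-disequilibrium blocks and a binary
    (log-odds) outcome so every stage of the screening workflow is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
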