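Package: mrkit
Title: Two-Sample Mendelian Randomization with Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) of continuous
    exposures (such as circulating cytokine concentrations) on binary and
    quantitative outcomes using GWAS summary statistics. Covers instrument
    selection (significance thresholds with a relaxed fallback, greedy LD
    clumping, proxy lookup against a local LD matrix, cis-restriction),
    exposure-outcome allele harmonisation including palindromic-variant
    frequency resolution, causal-effect estimation (Wald ratio,
    inverse-variance weighted, MR-Egger, weighted median), sensitivity
    analyses (Cochran's Q, leave-one-out, instrument F-statistics), a
    closed-form power calculation for binary outcomes, a grid driver for
    many-exposure by many-outcome analyses, and a seeded synthetic
    summary-statistic generator with known causal structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
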