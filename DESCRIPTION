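Package: metareduce
Title: Removing a Cohort's Contribution from Fixed-Effect GWAS Meta-Analysis Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inverse-variance fixed-effect meta-analysis (FEMA) of
    GWAS summary statistics and for the Meta-Reductive Approach (MRA): a
    closed-form algebraic adjustment that removes one constituent cohort's
    contribution from a published meta-analysis result using only the overall
    effect size and standard error and that cohort's own summary statistics.
    The adjustment eliminates sample-overlap inflation when meta-analysed
    summary statistics are reused as polygenic-risk-score base data. Includes
    readers and writers for common summary-statistics dialects (canonical,
    METAL-style, PLINK-style), allele harmonization, a multi-study simulator,
    leave-one-out validation that certifies the adjustment against a direct
    re-meta-analysis, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
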