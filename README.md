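# metareduce

Removing one cohort's contribution from inverse-variance fixed-effect
GWAS meta-analysis summary statistics.

## The problem

Polygenic risk scores (PRS) are built from GWAS summary statistics, and the
largest available summary statistics usually come from meta-analyses. When a
cohort appears both in that base meta-analysis and in the sample where the
PRS is trained or evaluated, the overlap inflates the apparent predictive
performance. Re-running the meta-analysis without the overlapping cohort is
often impossible — the constituent summary files may be inaccessible — but
it is also unnecessary. In an inverse-variance fixed-effect meta-analysis
(FEMA) the combined estimate is a precision-weighted sum, so one cohort's
contribution can be removed **in closed form** from the overall result and
that cohort's own summary statistics alone. The result equals a direct
re-meta-analysis of the remaining studies exactly; it is an algebraic
identity, not an approximation.

## The method

Each study *i* contributes an effect estimate β<sub>i</sub> with standard
error se<sub>i</sub> and weight w<sub>i</sub> = 1/se<sub>i</sub>².
The fixed-effect combination is

> B = Σ β<sub>i</sub> w<sub>i</sub> / Σ w<sub>i</sub>,  SE² = 1 / Σ w<sub>i</sub>.

Given the published (B, SE) and the overlapping cohort's (β<sub>n</sub>,
se<sub>n</sub>), the adjusted (cohort-removed) statistics are

> B<sub>adj</sub> = B + SE² (B w<sub>n</sub> − β<sub>n</sub> w<sub>n</sub>) / (1 − SE² w<sub>n</sub>),  SE²<sub>adj</sub> = SE² / (1 − SE² w<sub>n</sub>),

computed internally in the equivalent precision form
(B·W − β<sub>n</sub>w<sub>n</sub>)/(W − w<sub>n</sub>) with W = 1/SE², which
is robust when the cohort carries nearly all of the weight.

The package provides the scalar algebra (`fema()`, `mra_remove()`,
`wald_stats()`), a table-level workflow for summary-statistics files with
allele harmonization (`read_sumstats()`, `harmonize()`, `adjust_table()`,
`write_sumstats()`), a multi-study simulator (`simulate_studies()`),
leave-one-out validation (`leave_one_out()`, `compare_mra_vs_loo()`,
`reconstruct_from_loo()`), and a CLI
(`system.file("cli", "metareduce", package = "metareduce")`) with
`meta`, `remove`, `simulate` and `validate` subcommands.

## Worked example

The published single-marker validation: the association of the APOE ε4
allele with Alzheimer disease across four population-based studies
(African American, East Asian, Hispanic, non-Hispanic White). The four
published leave-one-out meta-analysis rows are inverted back to per-study
inputs, the full meta-analysis is fitted, and one population is removed:

```r
library(metareduce)

loo <- apoe4_loo()                       # published leave-one-out (beta, se)
rec <- reconstruct_from_loo(loo$beta, loo$se, labels = loo$study)
rec$meta
#> Fixed-effect meta-analysis estimate (4 studies, 1 marker(s))
#>       beta        se
#> 1 1.168518 0.0158784

summary(mra_remove(rec$meta, rec$studies[[1]]))   # remove African American
#> Inverse-variance fixed-effect meta-analysis (3 studies)
#>
#>       beta         se        z p
#> 1 1.189193 0.01671915 71.12758 0
```

The full four-study meta-analysis gives a log odds ratio of 1.1685
(OR ≈ 3.2) with SE 0.0159. Removing the African American cohort yields
B_adj = 1.189192599, SE_adj = 0.01671915 — identical, to every printed
digit, to the published meta-analysis of the remaining three studies. The
z of 71 reflects the enormous single-marker effect of APOE ε4.

At simulation scale (10 studies × 10,000 markers, Normal(0, 1) effects,
Uniform(0.1, 0.5) standard errors), removal agrees with a direct
leave-one-out re-analysis to machine precision for all 10 × 10,000
exclusions:

```r
studies <- simulate_studies(seed = 42)
compare_mra_vs_loo(studies)
#> Cohort-removal vs leave-one-out comparison
#>   comparisons:            100000 (study x marker)
#>   max |diff| beta:        1.11e-15 (rel 8.58e-15)
#>   max |diff| SE^2:        1.73e-17 (rel 1.27e-15)
#>   verdict at tol 1.0e-08:    PASS
```

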