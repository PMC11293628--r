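---
title: "Cohort removal from fixed-effect meta-analysis summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort removal from fixed-effect meta-analysis summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metareduce)
```

## The model

An inverse-variance fixed-effect meta-analysis (FEMA) assumes every study
estimates one common true effect. Study $i$ reports $(\beta_i, se_i)$ and
receives weight $w_i = 1/se_i^2$, the precision of its estimate. The
combined estimate is the precision-weighted mean

$$B = \frac{\sum_i \beta_i w_i}{\sum_i w_i}, \qquad SE^2 = \frac{1}{\sum_i w_i}.$$

Because both the weighted effect sum and the total precision are plain
sums, one study's terms can be subtracted back out of a published result.
Writing $W = 1/SE^2$ for the total precision and $(\beta_n, w_n)$ for the
cohort to remove,

$$B_{adj} = B + \frac{SE^2\,(B w_n - \beta_n w_n)}{1 - SE^2 w_n},
\qquad SE^2_{adj} = \frac{SE^2}{1 - SE^2 w_n}.$$

The adjusted pair equals a direct re-meta-analysis of the remaining
studies *exactly*: this is an algebraic identity, valid for any effect and
weight configuration, and is therefore distribution-free. Everything the
validation machinery in this package does is a consequence of that
identity.

The assumptions are those of the fixed-effect model and of the input
files: (1) the published meta-analysis is inverse-variance fixed-effect —
sample-size- or z-weighted schemes and random-effects models do not admit
this subtraction and are out of scope; (2) the cohort's summary statistics
are the same ones that entered the meta-analysis (same trait scale, same
genome build, same model); (3) effects are on an additive scale (log odds
ratio or linear-trait units) — odds ratios must be log-transformed first,
which `read_sumstats(or_scale = TRUE)` does explicitly and only behind
that flag, because silently mixing scales corrupts the algebra.

## Numerical design

**Precision form.** The displayed formula divides by $1 - SE^2 w_n$, a
subtraction that cancels catastrophically when the cohort carries nearly
all of the weight. Internally `mra_remove()` computes

$$B_{adj} = \frac{B W - \beta_n w_n}{W - w_n}, \qquad W_{adj} = W - w_n,$$

which is the same expression multiplied through by $W$, keeps the total
precision exact, and remains accurate at extreme weight fractions (the
test suite includes a cohort carrying 99.99% of the total weight).

**Dominance guard.** Removal is refused when
$1 - SE^2 w_n \le \varepsilon$ (default $\varepsilon = 10^{-12}$,
configurable): at that point the cohort *is* essentially the whole
meta-analysis — the limiting case being removal of the sole study — and
the division amplifies numerical noise into the result. In table-level
runs (`adjust_table()`) a dominated marker is flagged and emitted
unadjusted rather than aborting a genome-wide run; the same policy applies
to markers that are absent from the cohort, palindromic, or
allele-incompatible.

**Conditioning.** In double precision the floating-point agreement between
removal and a direct leave-one-out re-fit degrades linearly in the
removed-weight condition number $W/W_{adj}$: roughly
$10^{-16} \cdot W/W_{adj}$ relative. At realistic GWAS weights (standard
errors within a couple of orders of magnitude of each other,
$W/W_{adj} \lesssim 10^4$) agreement is $\sim 10^{-12}$ or better, and the
randomized property suites assert $10^{-10}$ with that headroom, drawing
standard errors log-uniformly from $[0.01, 1]$. Pathological dominance
beyond that is covered by the dedicated adversarial test and by the guard,
not by random draws — no tolerance can make a $10^{8}$-conditioned
subtraction reproducible to $10^{-10}$ in doubles.

**Comparison metric.** Squared standard errors are strictly positive, so
the validator compares them by pure relative difference. Effect sizes are
signed and cross zero, where relative difference is ill-defined
(machine-level noise divided by a vanishing reference); near zero the
validator therefore measures the difference on the estimate's own
standard-error scale: $|\Delta\beta| / \max(|\beta|, se)$. The default
pass tolerance of `compare_mra_vs_loo()` is $10^{-8}$ — far below any
printed GWAS precision, far above double-precision rounding — so a formula
or harmonization error is caught instantly while a correct implementation
passes on any valid input.

**P-values.** Input p-values are informational only. Output p-values are
recomputed as two-sided Wald normal tests, $p = 2\Phi(-|B/SE|)$; nothing
ever "adjusts" a p-value directly.

## Harmonization

The cohort's $\beta_n$ must refer to the same effect allele as the
meta-analysis $B$. Markers are matched by identifier only (positions are
carried but never used for matching; summary rows are the unit of
operation, 1-based coordinates by GWAS convention). Per marker the allele
pairs are compared case-insensitively, with strand complementation applied
before declaring a mismatch:

* identical pairs (directly or on the opposite strand) — `match`;
* swapped effect/other alleles — `flip`, the cohort beta is negated;
* A/T and C/G variants — `drop_palindromic` under the default policy,
  because their strand cannot be resolved from alleles alone; set
  `palindromic = "keep"` only when both files are known to report the same
  strand;
* anything else — `drop_mismatch`.

Dropped and missing markers are emitted unadjusted with `adjusted = FALSE`
(configurable to `missing = "drop"`): the conservative default never
fabricates an adjustment. An adjustment record — action, removed-weight
fraction $SE^2 w_n$, flags — is produced for every meta marker, so no row
leaves the pipeline untraced. If the meta file lacks allele columns
entirely, matching falls back to marker ID with a warning and the records
are flagged; this mirrors how published meta-analysis files sometimes omit
allele information, but it assumes both sources are pre-aligned.

## The simulator

`simulate_studies()` generates the structure used to certify the algebra:
`n_studies` tables over a shared synthetic marker set, every beta an
independent draw from Normal(`beta_mean`, `beta_sd`) and every SE an
independent draw from Uniform(`se_min`, `se_max`). The defaults — 10
studies × 10,000 markers, Normal(0, 1), Uniform(0.1, 0.5) — are the
package's reference conditions for full-scale validation, and the suites
run them as such.

Two deliberate simplifications. First, betas are independent across
studies: there is no shared true effect, so the "meta-analysis" averages
noise. That is sufficient — and appropriate — because the property being
validated is the distribution-free removal identity, which holds for any
configuration of betas and weights; a shared-signal generative mode is
deliberately not provided. Second, the tables carry constant synthetic
alleles (effect A, other G) so they pass harmonization unchanged. Passing
tests on simulated data therefore certify the algebra and the table
plumbing; they say nothing about LD structure, allele-frequency spectra,
case/control sampling, or real harmonization pathologies (strand mixes,
indel notation variants), which real inputs do exhibit. Draws use R's
default Mersenne-Twister stream in a fixed order (per study: betas, then
SEs), so a seed reproduces byte-identical tables across platforms.

## Reconstructing study inputs from leave-one-out results

`reconstruct_from_loo()` inverts the leave-one-out construction: given the
$k$ pairs $(B_{-i}, SE_{-i})$ of meta-analyses each excluding study $i$,
with $P_i = 1/SE_{-i}^2$,

$$W = \frac{\sum_i P_i}{k-1}, \quad w_i = W - P_i, \quad
S = \frac{\sum_i B_{-i} P_i}{k-1}, \quad
\beta_i = \frac{S - B_{-i} P_i}{w_i},$$

recovering the per-study inputs and the full meta-analysis $B = S/W$,
$SE = \sqrt{1/W}$. The system is exactly determined for $k \ge 3$ and the
solution is unique. $k = 2$ is rejected rather than guessed: each
leave-one-out result is then simply the other study, and the leave-one-out
standard errors fix no overall precision scale. A family of pairs that did
not arise from a coherent fixed-effect leave-one-out (for example, one SE
perturbed) produces a non-positive reconstructed weight and is rejected
with an explanatory error. This inversion is what makes a published
leave-one-out table — such as the four-population APOE ε4 family shipped
in `apoe4_loo()` — a complete, self-contained test of the removal algebra:

```{r apoe4}
loo <- apoe4_loo()
rec <- reconstruct_from_loo(loo$beta, loo$se, labels = loo$study)
mra_remove(rec$meta, rec$studies[[2]])  # remove the East Asian study
```

Feeding the reconstruction back through `leave_one_out()` reproduces the
published rows to every printed digit. Note the reconstruction is
self-consistent by construction; it recovers *a* study family whose
leave-one-out results are the published ones, which for a fixed-effect
family is the unique one.

## Design choices that were genuinely open

* **Ambiguity in the displayed adjustment formula.** Rendered flat, the
  closed form can be misread with the leading $B$ inside the fraction.
  That reading fails the simplest possible check — removing one of two
  identical studies must return the other — while the reading implemented
  here satisfies it and reproduces the leave-one-out re-fit identically;
  the intermediate weighted-sum rearrangement forces the same conclusion.
  The unit suite pins the two-identical-studies case explicitly.
* **Dialect support.** Input format is an engineering choice: three
  header conventions (canonical, METAL-style, PLINK-style) are recognized
  case-insensitively and auto-detected, and the writer emits the canonical
  dialect with 17-significant-digit serialization so round trips are
  bit-exact. Rows with non-positive or missing standard errors are
  rejected individually with a per-row trace, never silently.
* **Effect-size units.** The package never guesses units. The APOE ε4
  effects are consistent with a log-odds scale ($\beta \approx 1.19
  \Rightarrow OR \approx 3.3$); the algebra is unit-agnostic as long as
  meta and cohort share the scale.
* **`n_studies` is optional** on a combined estimate because published
  meta-analysis files rarely state it; the count is tracked when known and
  decremented on removal, skipped when unknown.

## Problem sizes

The shipped validation runs at the reference scale: the full 10 × 10,000
simulation for the identity check (all ten exclusions, ~10⁵ comparisons,
about a second), 1,000 randomized study sets per algebraic property
(precision conservation, SE monotonicity, removal-order independence,
reconstruction round trip, dominance-guard behavior), and the
single-marker four-population APOE ε4 reconstruction for the real-data
surface.

## Limitations

* Fixed-effect, inverse-variance meta-analyses only. Random-effects
  results, sample-size-weighted z-score meta-analyses, and heterogeneity
  statistics (Cochran's Q, I²) are out of scope.
* The adjustment is only as correct as the claim that the cohort truly
  entered the meta-analysis with exactly the supplied summary statistics.
  If the meta-analysis applied per-study genomic control or filtering, the
  published per-cohort file may not be what was combined, and the removal
  will be correspondingly off; the removed-weight fraction in the
  adjustment report is the first diagnostic to inspect.
* Palindromic variants are unadjustable under the default policy; with
  allele-frequency information one could resolve strand, but frequencies
  are deliberately outside this package's contract.
* No VCF parsing, liftover, imputation-quality filtering, multi-allelic
  decomposition, LD operations, or PRS construction.
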