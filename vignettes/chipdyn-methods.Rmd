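---
title: "Models and methods behind chipdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chipdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipdyn)
```

# The problem

Clonal hematopoiesis of indeterminate potential (CHIP) is the age-related
expansion of a blood-cell lineage carrying a somatic driver mutation in a
gene such as *DNMT3A*, *TET2* or *JAK2*. A clone is observed indirectly
through the variant allele fraction (VAF) of its driver mutation in a blood
draw: for a heterozygous autosomal mutation, VAF is about half the mutant
cell fraction, and the conventional threshold for calling CHIP is VAF >= 2%.
When the same individual is sequenced at two timepoints, the change in VAF
carries information that a single draw cannot: how fast the clone is
growing, whether it is shrinking, and — in individuals with two driver
mutations — whether the two mutations ride in the same cells (a nested
sub-clone) or in separate cell populations (distinct clones).

chipdyn implements this two-timepoint analysis as a reusable pipeline over
targeted-panel somatic calls, together with a ground-truthed synthetic
cohort generator, so that every stage can be exercised and validated without
access to protected biobank data.

# Variant filtering

Input calls (Mutect2-style VCF with per-sample `DP` and `AD`) are reduced to
CHIP calls by three per-record rules plus a panel-membership rule:

* total read depth >= 100 (depths below 100 are removed);
* alt-supporting reads >= 3;
* VAF >= 2% (computed as `AD/DP`, never taken from caller AF tags, so the
  same record filters identically across callers);
* the site lies inside the panel's targeted intervals.

All thresholds sit in `chip_filter_policy()` and the 2% rule is applied
inclusively: a VAF of exactly 0.02 passes. The shipped default panel covers
the 22 genes routinely used for CHIP calling over ~45 kb. Its interval
coordinates are representative regions (hotspot windows for genes like
*JAK2* or *IDH1/2*, broader coding territory for *DNMT3A*, *TET2*, *TP53*),
not a vendor capture design; deployments should substitute their own BED.

## Cross-timepoint rescue and the 0.001 floor

A mutation only needs to pass the filters at *one* timepoint to define a
clone. For the other timepoint:

* if a raw call matching the exact mutation key (contig, pos, ref, alt)
  exists with >= 3 alt reads, its VAF is used even when it is below 2%
  ("rescue"). Deep targeted panels genuinely measure VAFs down to a few
  tenths of a percent, so sub-threshold calls are usable evidence rather
  than noise;
* otherwise the VAF is imputed at 0.001, the assay's effective lower
  detection limit.

Rescued VAFs are floored at 0.001 so every clone pair satisfies
`vaf in [0.001, 1]`. Mutation identity across timepoints is an exact key
match; nearby indel representations are not fuzzy-matched (a documented
limitation). Individuals flagged with a blood-cancer diagnosis in the
metadata are removed before pairing — such clones reflect malignancy, not
CHIP — and the flag is an input, never computed here.

# The growth model

Each clone pair (VAF~1~, VAF~2~, elapsed time $t$ in years) is summarized by
its clonal fitness $CF$, the annual proportional growth rate under
deterministic exponential growth:

$$\mathrm{VAF}_2 = \mathrm{VAF}_1 (1 + CF)^{t},
\qquad
CF = \left(\frac{\mathrm{VAF}_2}{\mathrm{VAF}_1}\right)^{1/t} - 1 .$$

`compute_growth_rate()` evaluates the inverse in log space,
`exp(log(v2/v1)/t) - 1`, which is exact for the algebraically forced cases
(quadrupling over two years gives exactly 1.0 in double precision) and
stable for the extreme ratios the 0.001 floor produces (0.001 rising to 0.5
within a year). `project_vaf()` is the forward model and clamps projections
at 1 with a warning. Elapsed time prefers draw dates (days / 365.25) and
falls back to age differences.

$CF$ is scale-invariant in the VAF pair and strictly increasing in VAF~2~;
the test suite verifies a project-then-recover round trip to 10^-10^ across
VAF~1~ in [10^-3^, 0.5], $CF$ in (-0.9, 5] and $t$ in [0.5, 15] (restricted
to trajectories that stay within the admissible VAF range, since the
forward model clamps beyond it).

# Trajectory classes and z-scores

Clones are classified cohort-wide:

* **stagnant** — the bottom 10% of clones by |CF| (nearest-rank:
  `ceiling(0.10 n)` clones). The implied |CF| cutoff is data-dependent and
  is reported (attribute `stagnant_cutoff`), not enforced; on realistic
  cohorts it lands near a 2-4%/year absolute growth rate.
* **expansion / reduction** — the remaining clones by the sign of CF.

Ties in |CF| are broken by (individual, mutation key) lexicographic order so
assignments never depend on input order; a CF of exactly zero that escapes
the stagnant set is labeled expansion (a measure-zero case under continuous
growth rates). Within each class, CF values are standardized with the
sample (n-1) SD; singleton or zero-variance classes get z = 0 so that z-gap
comparisons stay defined.

# Sub-clone versus distinct clones

For individuals with exactly two retained mutations:

* clones in **different trajectory classes** are growing in different
  directions and are called **distinct**. This includes stagnant versus
  non-stagnant pairs: z-scores are standardized within a class and are not
  comparable across classes, so "same direction" is defined as same class;
* clones in the same class are **sub-clonal** when their z-score gap is
  below 0.6 and **distinct** at 0.6 or above (the boundary itself is
  distinct).

Individuals with three or more mutations receive trajectories but no
architecture call. The rule is a heuristic on two noisy growth estimates,
not a phylogenetic reconstruction: on synthetic cohorts simulated with
strongly separated growth rates the test suite reports its recovery rate,
which is an upper bound on real-data accuracy.

# Cohort statistics

**Per-gene summaries.** Arithmetic mean and SD of CF per driver gene with
trajectory-class counts; genes with fewer than 10 clones are reported but
flagged as below the ranking threshold. A sensitivity variant restricts to
individuals with a single retained mutation and reports the fraction of
clones and of individuals removed.

**Driver-gene co-occurrence.** Each two-mutation individual contributes one
unordered gene pair. Under the null, the two drivers are independent draws
from the cohort's driver-gene prevalence (marginal frequencies among all
retained mutations): $E\{g,h\} = 2 n p_g p_h$ for $g \ne h$ and
$n p_g^2$ on the diagonal (same-gene pairs are legal cells). The statistic
is $\sum (O-E)^2/E$ over all unordered pairs of observed genes. Because
expected cells are far below the classical chi-square regime at realistic
cohort sizes (tens of pairs spread over dozens of cells), the analytic
chi-square tail (df = cells - 1) is complemented by a seeded permutation
p-value that resamples pairs from the prevalence distribution; the
permutation variant is the one to trust when cells are sparse, and the toy
cases in the test suite show where the two agree.

**Covariate associations.** For each participant characteristic (age, sex,
race, ethnicity, BMI, height), a regression of CF on the covariate with
driver-gene indicator terms, one row per clone. Numeric covariates use
ordinary least squares on `cf ~ covariate + gene`; two-level covariates can
alternatively be modeled by logistic regression of the covariate on
`cf + gene`; factors with 3+ levels report the covariate's overall F-test.
Zero-variance covariates are skipped with a warning and designs collinear
with the gene terms are flagged, never silently dropped.

One modeling caveat is deliberate: with one row per clone, clones of the
same individual share covariate values, and nested sub-clones have nearly
identical growth rates, so the OLS rows are clustered and p-values are
somewhat anticonservative on multi-clone cohorts. This is a property of the
one-row-per-clone estimand (and one reason the single-mutation sensitivity
analysis exists). The suite therefore checks null calibration — type-I
error within the binomial 95% CI at alpha = 0.05 over 200 simulated
cohorts — on single-mutation cohorts, where the independence assumption
actually holds.

# The synthetic cohort generator

`simulate_cohort()` draws, per individual: a mutation count (1/2/3 with
probabilities 0.66/0.26/0.08 — individuals with "three or more" mutations
are given exactly three, since downstream analyses only distinguish 1/2/3+);
driver genes from a prevalence map skewed toward *DNMT3A* and *TET2*; true
first-draw VAFs log-uniform on [0.02, 0.30]; and true growth rates from
gene-specific normal distributions truncated above -0.95. True second-draw
VAFs follow the exponential model, capped at 0.5 (a heterozygous autosomal
clone cannot exceed the full cell fraction). First-draw ages are normal
(65 +/- 15, truncated to 18-91), draw intervals uniform on 1-12.5 years, and
sequencing is depth ~ Poisson(1725), alt reads ~ Binomial(depth, true VAF).
Demographics (60% female, 81% Caucasian, BMI 28 +/- 5, height 170 +/- 10 cm)
are drawn independently of growth, so the generator injects no covariate
effects.

Two-mutation individuals are nested sub-clones with probability 14/26: the
child clone starts below the parent's VAF, inherits the parent's growth rate
plus a small jitter (SD 0.02/yr), and its cell fraction is capped at the
parent's at both draws. Distinct clones are drawn independently.

Choices the data do not pin down, made once for testability and
configurable in `sim_config()`:

* **within-gene growth SDs** (0.20 for *DNMT3A*/*TET2*, 0.60 for *JAK2*,
  0.25 default): wide enough that trajectory classes and z-scores are
  non-degenerate, narrow enough that per-gene means are recoverable at a
  few hundred clones;
* **log-uniform first-draw VAFs**: clone sizes span the 2-30% range with
  the small-clone excess deep panels actually see;
* **exactly-two-timepoint design**: matching the paired-draw analysis; the
  generator does not emulate 3+ draw series.

What the generator deliberately does *not* emulate — and hence what passing
tests do and do not show: growth is deterministic exponential plus sampling
noise, with no stochastic population dynamics (no Wright-Fisher or
branching-process drift), no clonal interference beyond the nested-pair
cap, no mosaic chromosomal alterations, no X-linked or copy-neutral-LOH
VAF distortions, and symmetric within-gene growth variation. Two visible
consequences: fast clones (e.g. *JAK2* at a configured mean of 1.09/yr)
often hit the 0.5 VAF ceiling over long draw intervals, so their realized
mean growth is well below the configured mean — parameter-recovery checks
therefore compare estimates against the *realized* per-clone ground truth,
not the configured gene means; and the symmetric normal growth model yields
a lower expanding fraction than the strongly expansion-skewed cohorts
reported in real longitudinal CHIP studies. Passing tests demonstrate that
the estimator and classifiers are correct under the stated model, not that
real cohorts satisfy the model.

# Numerical and engineering choices

* Growth rates in log space; exact algebra confirmed for forced cases.
* BED intervals are 0-based half-open, VCF positions 1-based; the
  conversion lives in one function, and per-gene intervals are merged with
  `IRanges::reduce`.
* Multi-allelic VCF records decompose per alt allele, each against the site
  `DP`.
* Degenerate inputs flow through: empty VCFs produce empty, well-typed
  outputs with zero counts at every stage.
* All randomness (simulation, permutation test) is funneled through
  explicit seeds; identical config + seed reproduce byte-identical
  fixtures and pipeline outputs.
* Problem sizes in the test suite — 10^4^ round-trip triples and filter
  records, 1000 brute-force classifier cohorts of up to 12 clones, one
  500-individual parameter-recovery cohort at 2000x, 200 null-calibration
  cohorts of 101 individuals, 10^5^ detection-limit replicates — were
  chosen so each check has clear statistical resolution while the whole
  suite stays comfortably interactive.

# Known limitations

* Exact-key mutation matching across timepoints; shifted indel
  representations would split one clone into two half-observed ones.
* The architecture heuristic cannot see nesting when both clones grow at
  similar rates in the same class by coincidence; it is reported as-is.
* The co-occurrence analytic p-value leans on a chi-square approximation
  that is poor in sparse tables; prefer the permutation p there.
* Per-gene qualifying-variant whitelists (specific hotspots and consequence
  classes per gene) are not enforced beyond panel membership plus the
  depth/alt/VAF filters; annotation columns (`protein_change`,
  `consequence`) are consumed if present but not validated.
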