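---
title: "Methods: models, parameters and design choices in pdcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in pdcscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcscreen)
```

`pdcscreen` chains five analysis stages — somatic variant filtering,
read-depth copy-number calling, dose–response fitting, a drug×genotype
association screen, and cohort statistics — behind a synthetic-data module
that generates every input with known ground truth. This vignette is the
package's own account of the underlying models, the parameters that
matter, the numerical choices, and what the tests do and do not
demonstrate.

## Somatic variant filtering

A candidate is retained iff it clears **all** of: tumor depth ≥ 30 reads;
normal-sample variant allele fraction (VAF) ≤ 0.03; signed tumor−normal
VAF difference ≥ 0.05; strand bias (majority-strand fraction of alt reads)
≤ 0.9; alt-supporting reads ≥ 5; population frequency ≤ 0.015; an effect
class on the retained list; and, by default, not flagged as near a tandem
repeat. Decisions are total: every failing record lists *all* criteria it
violates, which is what makes the criterion-completeness tests possible.

Boundary semantics are read literally from how each threshold is usually
stated: "minimum/maximum ... is X" thresholds are inclusive (≥30, ≤0.03,
≥0.05, ≤0.9, ≥5), while the population filter removes strictly >0.015 —
so a candidate at exactly 0.015 survives. The VAF difference is signed
(tumor minus normal), not absolute: a somatic gain of allele fraction is
the target, and a variant enriched in the normal should fail. Strand bias
is taken as an input field (max of alt-forward/alt-reverse over alt
total); sequencing pipelines differ in how they define it, so alternative
definitions can be precomputed upstream. Synonymous variants are retained
by default — cohort spectrum summaries count them. No minimum normal-sample
coverage is enforced; none is part of the stated criteria.

## Read-depth copy number

**Normalization.** Per-bin tumor/normal count ratios are median-centered
(absorbing library-size differences; the same multiplicative factor on
both samples provably cancels) and divided by a GC-stratified median —
deciles of observed GC, with strata holding fewer than 20 bins borrowing
the global median. A decile-median correction is monotone and robust; a
spline fit would be smoother but can chase copy-number structure when GC
correlates with position. Bins with zero normal coverage are masked, never
divided. The output is the log2 of the corrected ratio.

**Segmentation.** Per chromosome, adjacent bins are greedily merged bottom
up. Each candidate merge is scored by its residual-sum-of-squares increase
in units of the bin-level noise variance (estimated from the median
absolute successive difference, a breakpoint-insensitive estimator);
merging continues while the cheapest merge costs less than a Bayesian
information criterion penalty `penalty × log(n)` per removed segment. The
penalty defaults to 2 and is exposed as configuration: larger values give
fewer segments. After merging, each breakpoint is refined locally — shifted
within a 10-bin window to the exact RSS-minimizing split of its two
flanking segments — which removes the 1–3-bin boundary bias that greedy
merging can leave on noisy data. Noise-free input recovers breakpoints
exactly, and constant input yields one segment per chromosome. Segment
means equal member-bin means, so the segmentation is an exact partition.

**Calls.** Segments are gains at log2 ratio strictly > 0.7 and losses
strictly < −0.7 (ratio ≈ 1.62 and 0.62; the log base is taken as 2, the
convention of read-depth CNV analysis). A gene is called when strictly
more than 75% of its exons overlap (≥ 1 bp) called segments of one
direction; 3 of 4 exons (exactly 0.75) is therefore neutral. If both
directions exceed the threshold — possible only for genes with many exons
split across a gain and a loss — the larger fraction wins and an exact tie
is neutral with a warning. Genes with exons on multiple chromosomes are
rejected with a warning. Coordinates are 0-based half-open throughout.
Bin size defaults to 1 kb in the simulator; both it and the penalty are
configuration, since neither has a canonical value.

## Dose–response and IC50

Viability is modeled as the four-parameter logistic
`v(c) = bottom + (top − bottom) / (1 + (c/EC50)^h)`, fitted by
Levenberg–Marquardt least squares with the midpoint parameterized as
log(EC50). Initialization is multi-start: a data-driven midpoint (the
concentration whose mean response is closest to halfway between the
response extremes) plus the median log-concentration, each with Hill slope
±1; the best RSS wins, and iteration stops early once the RSS is
negligible relative to the response spread. The optimizer is used through
its raw residual interface rather than a formula front end, because
formula-based wrappers reject perfectly converged solutions whose
saturated sigmoid tails make the final Jacobian numerically singular. The
fit is canonicalized to top ≥ bottom by flipping the Hill slope's sign,
which leaves the curve unchanged. Constant-response data give a flagged
degenerate fit rather than an error.

The IC50 is **absolute**: the concentration where the fitted curve crosses
0.5 on the viability-fraction scale (50% inhibition of untreated
control), not the halfway point between fitted top and bottom. When the
crossing lies outside the tested range or does not exist, the result is
censored `above_max` or `below_min`. Censored IC50s are excluded from
replicate means and surfaced as counts; when every experiment of a pair is
censored, downstream group comparisons receive the censoring bound (the
max or min tested concentration) with a flag, preserving group sizes
rather than silently dropping lines. Default mode fits one curve per
independent experiment and averages the IC50s — matching how replicate
means and SDs are usually reported — with pooled fitting available by
flag. Treatment duration is metadata only; it does not enter any
computation.

## Association screen

For each drug × (gene, alteration-kind) pair, carrier and non-carrier
IC50s are compared by a two-sided unpaired t test — pooled-variance
Student's t by default (Welch by flag), on the raw IC50 scale by default
with log10 as an option. The screen's family rules: pairs with both
groups of size ≥ 2 are tested and form the Benjamini–Hochberg family;
pairs where one group has exactly one line are kept in the output with
p missing and FDR forced to 1 (forcing rather than testing keeps
single-line anecdotes visible without diluting the correction); pairs
with an empty group are dropped. Degenerate inputs are explicit: zero
variance in both groups gives t = 0, p = 1 at equal means and a flagged
p = 0 at unequal means.

Candidates are selected at the largest FDR gap: records sorted by
ascending FDR (ties broken by descending |log10 effect ratio|, then
name), and the gap index is the rank `i < k_max` maximizing
`fdr[i+1]/fdr[i]`, with zero FDRs floored at 1e-300. A screen where every
FDR is equal has no gap and no candidates. Whether such a screen should
test raw or log IC50, and whether singleton pairs belong in the BH
family, cannot be settled in general; both are options with the defaults
above.

## Cohort statistics

Recurrence tables report per-event counts and cohort fractions at full
precision (display rounding to integer percent is left to the caller);
the optional display filter keeps events strictly above a recurrence
threshold. Co-occurrence of two events uses inclusion–exclusion
(|A∪B| = |A| + |B| − |A∩B|) plus the Jaccard index. Survival uses the
Kaplan–Meier product-limit estimator and the standard two-group log-rank
test (hypergeometric expectations and variances summed over event times,
1-df chi-square, no continuity correction). The Wilcoxon rank-sum test
enumerates all `choose(n+m, n)` assignments exactly when `n + m ≤ 12` and
there are no ties — at the group sizes of a small PDC panel the exact null
is cheap and has no approximation error — and otherwise uses the normal
approximation with continuity and tie correction. Z-score normalization
uses the sample SD (n − 1), a declared convention; constant genes come
back as zero rows with a flag instead of NaN.

## The synthetic-data module

The generators define the study conditions the tests run under:

- **Cohort**: 161 samples; per-gene alteration probabilities default to
  recurrent ESCC events (CCND1 gain 0.42, MCL1 0.38, FGF4/FGF3 0.35,
  SOX2 0.34, FGF19 0.34, CDKN1B 0.30 gains; MST1R 0.30, CDKN2A 0.26,
  CDKN2B 0.13 losses; plus TP53/KMT2D/NOTCH1/PIK3CA/EP300 SNV events),
  drawn independently per sample.
- **Variants**: true somatic candidates constructed to clear every filter
  criterion with margin, with a C>T-dominated substitution spectrum and
  missense-heavy effect classes; artifacts planted at a configurable rate,
  each violating exactly one named criterion, with truth labels.
- **Coverage**: Poisson counts per bin (the simplest model consistent with
  read-depth data) around a GC-bias-scaled mean, the same bias applied to
  tumor and normal; tumor means additionally scaled by `2^log2ratio`
  inside planted segments. The default GC track mixes a slow wave with
  fine-scale scatter so GC strata sample bins genome-wide. A noise-free
  mode emits exact expected counts for algebraic tests.
- **Viability**: 8 lines × 46 drugs, 10 concentrations in an exact
  3.3-fold dilution series from 10 µM, quadruplicate; carrier lines'
  IC50s are the drug's base IC50 (default 1 µM) times the planted fold
  change, with the headline event carried by exactly 5 of 8 lines. Noise
  is multiplicative log-normal with unit mean and relative SD `cv_noise`
  (default 0.1) — the relative-error behavior of luminescence assays.
  Replicates are independent; real replicate correlation is not modeled.
  `simulate_ic50()` applies the same noise model directly at the IC50
  level, which is the distribution replicate-averaged fits produce and is
  what the large seed-sweep simulations use.
- **Survival**: exponential event times per group; censoring times are
  Uniform(0, b) with b solved so the expected censored fraction equals
  `censor_rate` — independent uniform censoring at a controlled rate.

Every generator takes an explicit seed; no global random state is used,
and identical spec + seed is bit-identical. What passing tests show is
that the pipeline recovers **planted** effects under these idealized
conditions — independent events, Poisson depth, log-normal noise, no
purity/clonality structure, no alignment artifacts, no read-level
simulation. They do not show robustness to correlated noise, batch
effects, or tumor heterogeneity, which real data have and the generators
deliberately omit.

## Verification set-up and problem sizes

The test suite and the acceptance script recompute, among others:
co-occurrence and cohort percentages exactly from printed counts
(41/21/18 of 161; 153/161; 8/123); BH against a brute-force step-up
oracle (families up to m = 20); exact Wilcoxon against full enumeration
(n + m ≤ 10) including the separated 5v3 two-sided p = 2/56 ≈ 0.0357;
log-rank against a hand hypergeometric-sum oracle; 4PL IC50 recovery over
100 seeded curves at 5% CV (median relative error, threshold 10%); CNV
breakpoint recovery within ±2 bins for planted |log2| = 1 segments of
100 bins at Poisson depth 100 over 20 seeds; screen recovery of a planted
fold-0.05, 5v3 effect on the 8 × 46 panel over 50 seeds (rank-1 rate,
threshold 90%); and null calibration of the screen over 100 seeds.

Two calibration details are deliberate. The null-calibration check uses a
99% t-interval of per-seed rejection fractions across the 100 independent
seeds rather than a pooled binomial interval, because tests within one
seed share line-level IC50 vectors across overlapping carrier groups and
are not independent Bernoulli draws; and it runs on the log10 scale,
where the log-normal noise model makes the t reference distribution
exact. The screen's default scale remains raw. Cohort-frequency recovery
is checked with a 3-SE band per event because all 15 events are checked
simultaneously.

## Known limitations

Segmentation is greedy and can in principle lock in a suboptimal merge
order (the refinement pass corrects boundaries, not segment counts); very
short segments near the noise floor may be absorbed. GC correction at
decile granularity cannot separate GC bias from copy-number structure if
a large CNV dominates a GC stratum. The 4PL fit reports best-effort
parameters with an honest `converged` flag rather than failing, so
downstream code should check diagnostics. Allele-fraction (BAF)
integration, purity/ploidy estimation, AUC/DSS response metrics,
drug-combination models, Cox regression and mutual-exclusivity statistics
are out of scope.
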