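---
title: "Methods: rare structural-variant replication analysis with gsvrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare structural-variant replication analysis with gsvrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsvrep)
```

## The problem

Rare genomic structural variants (GSVs — deletions and duplications, here
used interchangeably with CNVs) of large effect are a candidate source of the
"missing heritability" of complex traits such as obesity. Testing whether a
previously reported GSV–phenotype association replicates in new cohorts
requires a chain of steps, each with pitfalls of its own: deciding from
segment-level copy-number calls which samples truly carry a variant of the
expected class at a candidate locus; testing rare carrier counts with exact
statistics; knowing in advance how much power the design has at plausible
carrier frequencies and odds ratios; and recognizing that *differential* call
error between cases and controls manufactures false associations even when
no true effect exists. `gsvrep` implements this chain as composable,
separately testable pieces, together with a synthetic-cohort generator so the
whole pipeline can be validated against known ground truth.

## Carrier qualification

Inputs are candidate regions (1-based inclusive coordinates on genome build
hg18, each with an expected class, `gain` or `loss`, and a 500 kb flank), a
probe map emulating a SNP genotyping array, and segment calls
(`sample, chrom, start, end, integer copy number, probe count`) from an
upstream caller. Calling algorithms are out of scope: the package starts
where a caller's segment table ends.

Per sample and region the decision tree is:

1. Calls of the wrong class are discarded, as are calls covering fewer than
   `min_consecutive_probes` (default 3) array probes. Probe support is
   counted over the region *plus flank*, so a call at a region with only one
   or two in-region probes can still qualify by extending across flanking
   probes — without this, loci with sparse coverage could never yield a call
   at all.
2. A region with zero in-region probes is uncallable.
3. Below `merge_min_probes` (default 11) in-region probes, a sample is a
   carrier only if a single surviving call spans the entire region. The
   published criteria name only the "6 or fewer probes" and "11 or more"
   regimes; for regions with 7–10 probes we apply the full-span rule, the
   conservative reading consistent with the statement that every scored
   variant spanned its whole region.
4. At `merge_min_probes` and above ("merge mode"), callers tend to fragment
   long events, so the in-region probes of all surviving same-class calls
   are unioned; the sample is a *provisional* carrier if strictly more than
   `merge_fraction` (default 0.5) of in-region probes are altered. "Strictly
   more" matters at the boundary: 15 of 28 probes qualifies, 14 of 28 does
   not. In the original array workflow provisional calls were confirmed by
   manual inspection of raw intensities; that manual step cannot be
   automated faithfully, so the package instead flags such calls and emits a
   machine-readable review report (`provisional_report()`).

Reciprocal events (duplication where a deletion is expected, and vice versa)
are scored with identical criteria and the class inverted. Qualification is
deterministic and invariant to the order of input calls; in merge mode,
adding another matching-class call can only preserve or create carrier
status, never revoke it.

## Case-control association

Carrier counts are compared with Fisher's exact test (`stats::fisher.test`
conventions: the two-sided P sums the probabilities of all tables, at fixed
margins, no more probable than the observed one; the one-sided P is the
hypergeometric tail toward enrichment in the first group). The obese stratum
pools the obese case groups with obese members of the population cohort; the
non-obese stratum pools controls with normal-weight population members;
overweight individuals (25 ≤ BMI < 30 kg/m²) are excluded from the
comparison. Weight classes use the standard thresholds: obese ≥ 30, normal
< 25.

Effect sizes are reported two ways, deliberately:

* the **sample (cross-product) odds ratio** `(a·d)/(b·c)` with a Woolf
  log-scale interval — this is the estimator that reproduces the published
  pooled values (38.4 and 25.0) exactly to three significant figures;
* the **exact conditional maximum-likelihood estimate** with the
  Cornfield-type interval from noncentral hypergeometric tails — this
  interval reproduces the published confidence brackets ([10.4, 120.6] and
  [9.9, 60.6]) to their printed precision, identifying it as the interval
  behind them. Both estimators are emitted with method labels.

Carrier frequencies get Wald intervals `p ± 1.96·√(p(1−p)/n)` (these
reproduce the published population-frequency and case-fraction intervals);
Clopper–Pearson is available behind a flag. A side note on one published
value: the adult-vs-child comparison printed as 0.039 reproduces as the
*two-sided* exact P of 0/840 vs 10/1985 (the one-sided P is 0.029), so the
package's default two-sided convention covers it.

Multiple-testing adjustment wraps `p.adjust` (Bonferroni and
Benjamini–Hochberg).

## Exact power for rare carriers

Replication studies of rare variants live or die on power, and normal
approximations are useless at carrier frequencies of 10⁻³–10⁻⁴.
`fisher_exact_power()` computes the exact unconditional power of the
(default one-tailed) Fisher test: carrier counts in the two groups are
independent binomials; the power is the total probability of count pairs
whose realized 2×2 table rejects at level α. Binomial supports are truncated
where the per-margin tail mass falls below `truncation_eps` (default 10⁻¹²)
and the discarded mass is reported as a bound on the absolute error — so the
reported power brackets the untruncated value. The enumeration is a few
thousand hypergeometric tail evaluations and runs in well under a second for
cohort-scale designs.

For the pooled replication design (1,816 obese vs 4,526 non-obese), this
reproduces the published grid: ≈99%, 94% and 83% power at a case carrier
frequency of 0.005 for odds ratios 50, 10 and 5, and 67%, 53% and 40% at
0.002. `scripts/acceptance.R` recomputes exactly these numbers.

## Call-error inflation and genomic control

Under the null, both groups share a true carrier frequency *f*; per-group
false-positive and false-negative call probabilities turn this into an
observed frequency `p_obs = f(1−fn) + (1−f)·fp`. The identity makes the
mechanism transparent: symmetric error leaves `p_obs` equal between groups
and the null intact, while any case-control difference in fp or fn creates a
genuine difference in *observed* frequencies — an association of the error
process, not the genotype. `simulate_null()` draws replicate cohorts under a
`miscall_model()`, computes two-sided exact P-values, and reports empirical
type-I error, QQ coordinates and the genomic inflation factor
λ = median(χ²)/0.4549 after quantile-transforming P-values to 1-df
chi-squares. `gc_correct()` divides the χ² values by λ and transforms back.

Two numerical caveats are intrinsic and documented rather than hidden. First,
with very rare carriers the exact test is strongly discrete and
conservative, which *deflates* the median χ²: a clean null at counts of ~10
carriers per group yields λ well below 1, and λ-scaling correspondingly
under-corrects differential-error inflation at such counts (the package
messages when median observed counts are below 5). Genomic control is
therefore demonstrated, and tested, at error and frequency scales where
observed carrier counts are large enough (tens per group) for the χ²
transform to be informative; there it restores the empirical type-I error to
its nominal level. Second, the exact parameter grid of the original
supplementary analysis is not published; `inflation_grid()` ships a labelled
reconstruction (f ∈ {0.002, 0.005}, control fp ∈ {0, 0.001, 0.004},
case:control fp ratio ∈ {1, 2, 4}) as free parameters, and no quantitative
claim from that supplement is asserted.

## The synthetic-cohort generator

`generate_cohort()` emulates the study's inputs with known ground truth. Its
defaults *are* the study conditions: group sizes 557/645/843/701 for the
child and adult case-control cohorts and 5,213 for the population cohort;
the bundled `fixture_paper_regions()` reproduces the 18 candidate loci with
in-region probe counts matching the published coverage column exactly (0 to
207 probes), plus 12 synthetic probes per 500 kb flank.

* **BMI.** log₁₀ BMI ~ Normal(μ_sex, σ_sex) with μ = log₁₀(25.5) (M) /
  log₁₀(24.5) (F) and σ = 0.07. The source study does not publish its
  population BMI distributions; these values were chosen once to give a
  realistic adult obesity prevalence of roughly 15–20% and are asserted only
  for internal consistency. Case groups are truncated to obese
  (BMI ≥ 30), controls to non-obese (< 25), the population is unconstrained.
* **Effects.** Either an odds ratio on obesity status (carrier probability
  follows realized weight class: case frequency for obese, baseline for
  normal, odds-scale midpoint for overweight), a log₁₀-BMI shift for
  carriers, or an explicit per-region × per-group frequency matrix.
* **Call structure.** Carrier segments span the region with breakpoint
  jitter of up to `jitter_probes` flanking probes per end (breakpoints land
  on probe coordinates, as array callers report them). At merge-mode regions
  a call fragments into two sub-segments with probability
  `fragmentation_prob`; fragments always jointly cover more than
  `frag_min_coverage` (> 0.5 enforced at spec construction) of in-region
  probes and at least 3 probes each, so fragmentation never contradicts the
  ground-truth carrier state. False negatives suppress a carrier's call;
  false positives inject a qualifying call in a non-carrier; reciprocal
  variants are drawn among non-carriers.

What the generator does **not** emulate: raw intensity (LRR/BAF) noise,
linkage disequilibrium, family structure, population stratification, and
probe-level artifacts. Passing pipeline tests on synthetic cohorts therefore
demonstrates the correctness of qualification and inference given a
caller's segment output — not the accuracy of any upstream caller on real
arrays.

## Quantitative-trait analysis

For loci with at least `min_carriers` (default 3) carriers in the population
cohort, `anova_carrier_bmi()` fits `log₁₀BMI ~ sex + carrier` with
sequential (type-I) sums of squares, sex first — the classical two-way `aov`
idiom — and a joint mode fits several carrier indicators in one model
(several samples can carry more than one variant). A type-II decomposition
is available as an order-independent robustness check. Effects are
back-transformed to kg/m² via carrier vs non-carrier geometric means.
`carrier_mean_test()` is the Welch heteroscedastic t-test;
`zscore_test()` standardizes each carrier's BMI within its own cohort and
tests mean Z > 0 against the normal tail at `mean(Z)·√n`, with the interval
from the observed SD of the carrier Z's by default (the convention that
matches the published interval) and a unit-variance null alternative behind
a flag. `subgroup_contrast()` handles loci where variants of different
extent may act differently (the motivating case: large deletions reducing
BMI while small ones are neutral), including a single-observation Z fallback
when a subgroup has one member. The published per-locus ANOVA P-values
require individual-level BMI that is not printed anywhere; these operations
are therefore validated by simulation (type-I error, power at known shifts,
interval coverage), not against printed values.

## Calibration testing with a discrete exact test

A subtlety worth recording: P-values of an exact conditional test at rare
counts are discrete and stochastically *larger* than uniform, so a naive
Kolmogorov–Smirnov test of pipeline P-values against U(0,1) would fail for
any correct implementation. The test suite instead applies the randomized
probability integral transform conditional on each replicate's table
margins — `u = F(p⁻ | margins) + V·Pr(p | margins)` with V ~ U(0,1) — which
is exactly uniform under the null regardless of discreteness; the
conditional distribution is enumerated directly from hypergeometric
probabilities, independently of the implementation under test.

## Problem sizes and numerical choices

Simulation-based checks in the test suite use deliberately scaled designs:
null calibration runs 500 pipeline replicates of 600-sample cohorts at one
merge-mode locus; interval coverage uses 200 cohorts of 800 samples at a
simulated odds ratio of 10 with carrier counts large enough (~tens per
group) that the exact interval's conservatism stays mild; inflation runs
3,000 replicates of 5,000 + 5,000 cohorts. Power enumeration is exact, not
simulated, and is cross-checked once against 50,000 Monte-Carlo cohorts.
Other conventions: probe-in-interval counting is closed on both ends;
0-based half-open (BED) input is converted on read; the per-region
`size_bp` column is reported as `end − start`, matching the published locus
table's size column; ties in the minimum-likelihood two-sided sum use the
customary 1 + 10⁻⁷ relative tolerance.

## Known limitations

* Regions with 7–10 probes fall under the full-span rule by design decision;
  the original criteria are silent on this band.
* Whether "3 consecutive probes" in the original workflow counted all array
  probes or only call-informative ones is unknowable from the text; the
  package counts array probes in the region + flank window.
* λ-based genomic control is a blunt instrument for very rare discrete
  tests (see above); it is the established correction, not an optimal one.
* The generator's BMI model is a two-parameter log-normal per sex; real
  cohort BMI distributions are skewed, heteroscedastic across age, and
  cohort-specific.
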