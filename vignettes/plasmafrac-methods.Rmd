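---
title: "Methods: accounting and statistics for plasma EV fractionation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accounting and statistics for plasma EV fractionation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmafrac)
```

## The problem

Blood plasma carries extracellular vesicles (EV) at roughly 10^10 particles
per ml next to lipoprotein particles (LPP) that outnumber them by about six
orders of magnitude and soluble proteins that dominate the protein mass.
Separating EV well enough for unbiased omics requires two orthogonal
dimensions: size-exclusion chromatography (SEC), where large particles elute
early, followed by density-gradient centrifugation (ODG), where EV band at
1.09–1.10 g/ml and LPP at 1.04–1.07 g/ml. `plasmafrac` implements the
quantitative layer of that strategy: mass accounting across fractions,
label-free differential proteomics between the crude, LPP and EV extracts,
rule-based protein catalogues, and the small-RNA statistics — together with a
seeded synthetic generator so that every stage can be tested against known
ground truth.

## Fraction accounting

For an analyte $a$ with per-fraction amounts $x_{a,f}$ and whole-input total
$X_a$, the recovery over a fraction window $W$ is
$R_a(W) = \sum_{f \in W} x_{a,f} / X_a$, and the enrichment factor of analyte
$a$ over analyte $b$ is $E = R_a(W) / R_b(W)$. By algebra $E$ equals the
$a\!:\!b$ ratio inside the window divided by the same ratio in the whole
input, which is the conventional particle-per-protein enrichment statistic.
Depletion of a marker is the same quantity with the marker in the
denominator. Computation keeps full precision; the "$n$-fold" integers are
produced only at the presentation layer. Published fold figures are often
printed from already-rounded recoveries and then cannot be reproduced exactly
from the co-printed percentages (34%/1.1% gives 30.9, 34%/1.40% gives 24.3);
the package reproduces the arithmetic at full precision rather than any
particular rounding.

Windows are always explicit fraction-id sets (or density windows mapped to
fraction ids with `density_window_fractions()`); nothing is inferred from the
data. Recoveries slightly above 1 can arise from assay noise and are clamped
at `1 + tolerance` with a warning.

## The synthetic plasma and fractionation model

`make_default_plasma()` builds the reference composition: EV (120 nm median,
1e10/ml, density 1.095 ± 0.0067 g/ml, carrying CD9 and FLOT1), HDL (10 nm,
5e15/ml, 1.057 g/ml, carrying APOA1), LDL (22 nm, 1.5e12/ml, 1.055 g/ml) and
a large chylomicron/VLDL class (400 nm, 2e10/ml), each apoB-class particle
carrying one APOB unit, plus an albumin-dominated soluble background of
70 mg/ml. Total LPP outnumber EV by ~5e5.

SEC elution is a discretized Gaussian over fraction index whose mean falls
log-linearly with particle size (`peak = 13.19 - 3.7 log10(size_nm)`) and
whose spread grows with the peak position; this is the simplest monotone
size-to-fraction map that reproduces the observed elution order (large
particles first, HDL-sized analytes from fraction 7 onwards, soluble protein
last). ODG banding is a Gaussian over the per-fraction densities with
effective spread `sqrt(banding_sd^2 + class_density_sd^2)`. Weights are
renormalized over the available fractions and scaled by `1 - loss_fraction`,
so in lossless mode conservation is exact by construction (the test suite
asserts 1e-9 relative error).

Measurement noise is multiplicative log-normal with unit mean and a 10%
coefficient of variation per assay by default; published assay CVs are not
available for this workflow, and 10% is a realistic figure for ELISA/NTA
class measurements. The defaults were calibrated once, before any noisy
testing, to the benchmark marginal recoveries of the underlying fractionation
strategy: ~73% of CD9 in SEC fractions 5–6, ~1.4% of APOA1 there, >85% of
APOA1 and >95% of APOB of the crude extract in the 1.04–1.07 g/ml window, and
a CD9 maximum in the 1.09–1.10 g/ml fraction holding ~45% of the CD9 signal.
Because a single noisy run estimates a recovery with ~5% relative error, the
calibration checks estimate the defaults' expected recoveries by averaging
20 replicate simulated experiments.

The generator reproduces marginal recoveries, marker co-banding and
measurement noise. It does not model diffusion, sedimentation coefficients,
column overloading, inter-donor biological variability, or particle
aggregation; passing calibration says the shipped defaults encode the
intended marginal behaviour, not that real plasma behaves this simply.

## Label-free differential proteomics

The proteomics workflow mirrors the established Perseus-style pipeline on
log2 LFQ intensities:

* **Valid-value filter.** A protein is kept when at least one group has
  valid values in at least 66.67% of its replicates (`filter_valid()`, with a
  1e-9 slack so 4/6 passes the 2/3 rule).
* **Imputation.** Missingness in LFQ data is missing-not-at-random: low
  abundance drops out first. Missing cells are drawn from
  $N(\mu_j - 1.8\,\sigma_j,\ (0.3\,\sigma_j)^2)$ using each sample column's
  observed moments — the conventional down-shifted Gaussian; width and
  down-shift are configurable, and a whole-matrix variant is available by
  flag.
* **S0-moderated test.** $t_{s_0} = (\bar a - \bar b)/(s_0 + \mathrm{SE})$
  with the pooled (not Welch) standard error, matching the balanced designs
  this workflow targets, and $s_0 = 0.1$ by default. $s_0 = 0$ recovers the
  classical two-sample t exactly; increasing $s_0$ can only shrink the
  statistic.
* **Permutation FDR.** Group labels are permuted — exhaustively over all
  distinct splits when there are at most 10,000 (for 6 vs 6 that is 924),
  otherwise by seeded sampling with 250 draws by default. Each feature's
  q-value is the mean permuted count of statistics at least as extreme
  divided by the observed count, capped at 1 and monotonized by a cumulative
  minimum running from the least to the most significant feature; features
  with q below 0.05 are called significant. Two-sided throughout.

Descriptive companions: pairwise correlation matrices on shared observed
features with within/between-group medians, PCA on centred features,
hierarchical clustering with 1-Pearson or Manhattan distances (average or
Ward linkage; a constant item's undefined correlation distance is set to the
maximum, 2), kernel-density curves of per-feature differences (Gaussian
kernel, Silverman bandwidth, renormalized to unit area), and z-score series.
Whether z-scoring precedes clustering is left to the caller: both orders are
valid, so the package takes a plain matrix and the caller picks the
transform.

## Protein catalogues

Two rule-based catalogues formalize what co-fractionation does and does not
prove about EV association:

* **Putative non-EV-associated proteins**: identified in the crude extract
  (SEC co-elution with EV) *and* significantly enriched towards the LPP
  extract (different buoyant density), at q below `alpha` (default 0.05, on
  the corrected scale).
* **Putative EV-corona candidates**: identified in the crude extract,
  significantly enriched towards the EV extract (shared density), and
  annotated as secreted yet consistently identified in EV replicates (the
  same 2/3 presence rule).

"Present" means detected (valid, non-imputed) in at least 2/3 of a group's
replicates; direction comes from the sign of the group-mean difference and
significance from the permutation q-value. The two categories are mutually
exclusive by construction, and shrinking the crude presence set can only
shrink both catalogues. Corona abundance is related to blood-plasma
concentration by Spearman correlation with an exact enumerated p-value for
n up to 9 (all $n!$ rank pairings, built in batches); n = 10 already needs
3.6 million pairings, so from n = 10 the standard t-approximation is used.

## Small-RNA statistics

* **Detection filter**: keep a feature when some group shows a count of at
  least 1 in at least half (ceiling) of its samples. The stricter
  every-group reading is available via `require_all`; the disjunctive
  reading is the default because it matches the filter's purpose of
  retaining anything reliably detected somewhere.
* **Normalization**: median-of-ratios size factors over features nonzero in
  every sample, rescaled to geometric mean 1, with library-size fallback
  (and a warning) when no such feature exists.
* **Differential expression**: a transparent negative-binomial Wald test —
  log2 fold-changes from normalized group means with pseudo-count 0.5,
  pooled method-of-moments dispersion, delta-method standard errors,
  Benjamini–Hochberg adjustment — flagged DE at |log2FC| ≥ 1 and adjusted
  p ≤ 0.05. This is deliberately a documented simplified stand-in: the DE
  criteria are the scientific contract here, and a full shrinkage estimator
  (as in DESeq2) is out of scope; DESeq2 serves as an independent
  cross-check of the size factors in the tests.
* **Biotype composition**: proportions of summed counts per biotype among
  non-excluded biotypes, per group and overall.
* **Codon usage**: normalized tRNA-fragment counts pooled by amino-acid
  isotype per group, restricted to isotypes detected in at least 66.67% of
  *all* samples, renormalized, and contrasted as fold changes. Because the
  whole-plasma tRNA pool is glycine-dominated, most non-Gly isotypes appear
  relatively enriched in EV extracts — the synthetic default reproduces that
  qualitative pattern.
* **GSEA**: the classic (unweighted) running-sum enrichment score, +1/Nh at
  hits and −1/(N−Nh) at misses, ES the signed maximal deviation. Sample
  permutation is impossible on a single ranked list, so the null permutes
  which features carry the set label; NES divides ES by the mean same-sign
  permuted ES and p is the same-sign exceedance proportion with the +1
  pseudo-permutation. Ranking uses log2 fold-change, ties broken by mean
  normalized count and then feature id.
* **Mann–Whitney**: exact two-sided p by full enumeration of all
  $\binom{n_1+n_2}{n_1}$ assignments whenever $n_1+n_2 \le 20$ (complete
  separation at 6 vs 6 gives p = 2/924 ≈ 0.0022); larger samples use the
  tie-corrected normal approximation without continuity correction.

## Omics generators

`simulate_lfq()` draws log2 intensities as baseline (N(25, 2²)) plus planted
group shifts plus replicate noise (sd 0.5), then applies logistic
intensity-dependent dropout — the empirical missingness rate is
non-increasing in intensity decile by construction. `simulate_smallrna()`
draws negative-binomial counts (dispersion 0.1 by default; dispersion 0
falls back to Poisson) around means built from per-group biotype shares,
per-isotype tRNA shares, and Zipf-decaying within-biotype weights; planted
effects multiply means by 2^shift, and an optional geometric time-course
decays a designated miRNA across ordered samples. All randomness in the
package flows through one explicit seed per call, saved and restored around
the draw, so identical seeds give bitwise-identical output and calls never
disturb the caller's RNG.

## Pipeline and determinism

`run_pipeline()` executes simulate → fraction metrics → proteomics →
catalogues → small RNA from a single validated configuration (unknown keys
are rejected, ranges checked). Per-stage seeds are derived from the global
seed by a stable arithmetic hash of the stage name, so toggling one stage
never shifts another's randomness; the JSON run report is byte-identical
across repeated runs of the same configuration.

## Problem sizes and numerical choices

The shipped tests run the differential workflow at 1000 features with 6 vs 6
replicates (exhaustive 924-split permutation null), the catalogue recovery at
600 features with 83 planted LPP-only and 10 corona proteins, and the
calibration envelope over 20 replicate simulated experiments — sizes chosen
to mirror the workflow's real designs while keeping a full test run in well
under a minute per suite. Numerical conventions: conservation tolerance 1e-9
relative; filter boundaries carry a 1e-9 slack; exhaustive-permutation
threshold 10,000 splits; Spearman enumeration bound n ≤ 9; Mann–Whitney
enumeration bound n₁+n₂ ≤ 20; ties in ranks use averages; q and BH values are
capped at 1.

## Known limitations

The fractionation simulator is a marginal-recovery emulator, not a transport
model; the NB Wald test has no dispersion shrinkage and is anti-conservative
at very small counts; the permutation FDR estimator is the conventional
plug-in ratio and can be conservative at small permutation counts; corona
classification inherits any bias in the user-supplied secreted annotation;
and synthetic catalogues say nothing about the identity of real plasma
proteins — they test the rules, not biology.
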