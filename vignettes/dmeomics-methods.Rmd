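---
title: "Methods: probe-level arrays, internal-standard metabolomics, and diauxic growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-level arrays, internal-standard metabolomics, and diauxic growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmeomics)
library(dplyr)
```

`dmeomics` re-implements, as composable tibble-in/tibble-out functions, the
analysis workflow of a free-living *Sinorhizobium meliloti* malic-enzyme
mutant study: custom whole-genome expression arrays, GC-MS polar-metabolite
profiling against a ribitol internal standard, and plate-reader growth
curves with a diauxic shift on mixed carbon sources. This vignette explains
the models and procedures, the parameters that matter, what the synthetic
generators do and do not emulate, and the design choices made where the
original description left the method open.

## Microarray preprocessing and differential expression

The arrays carry roughly six 60-mer probes per annotated feature plus a
population of *null probes* that match no genomic sequence. The pipeline
is:

1. **Quantile normalization** across all arrays: each value becomes the
   mean, across arrays, of the values sharing its rank (the row means of
   the column-sorted matrix). Ties within an array receive the mean of the
   reference values their ranks span, so a run of equal intensities stays
   equal after normalization. This tie rule is implemented directly; on
   tie-free data it agrees with `limma::normalizeQuantiles`, which the test
   suite uses as an independent cross-check.
2. **Feature filter**: a feature is kept only if it is targeted by at least
   `min_probes = 6` *non-redundant* probes. Without probe sequences,
   non-redundant is interpreted as distinct `probe_id`; duplicated rows for
   one probe count once.
3. **Background**: the per-array background is the median null-probe
   intensity (the mean is available via
   `de_config(background_stat = "mean")`). The median is the default
   because a handful of null probes can cross-hybridize brightly, and the
   estimate should not follow them.
4. **Feature expression**: per feature and array, the median of the
   feature's probe intensities minus that array's background. Corrected
   values below `negative_floor = 1` intensity unit are set to the floor
   and flagged — ratios require positive values, and a floored feature's
   fold change is not trustworthy, so the flag travels with the result.
5. **Differential expression**: per feature, the ratio of the two
   experiments' replicate-averaged corrected values (not the average of
   per-replicate ratios), and a pooled-variance two-sample Student's *t* on
   the replicate-level values, two-sided, with df = n_a + n_b − 2. With the
   study's two replicate arrays per experiment this gives df = 2; a Welch
   test would have an ill-defined df there, which is why the pooled variant
   is used. Significance is the joint rule fold ≥ 3 **and** *P* ≤ 0.05. No
   multiple-testing correction is applied by default, deliberately
   mirroring the raw-*P* screen; `de_config(adjust_p = TRUE)` switches the
   call to Benjamini–Hochberg-adjusted p-values.

Degenerate variance cases are resolved explicitly: zero pooled variance
with equal means gives *t* = 0, *p* = 1; zero pooled variance with unequal
means is reported with *p* = 0 and a `degenerate` flag rather than NaN.

Whether the original *t*-test was applied to replicate-level corrected
values (n = 2 vs 2) or to probe-level values is not documented; the
replicate-level reading is implemented because the stated ratio is formed
from replicate-averaged values, and the probe-level alternative would
conflate probe-affinity variance with biological variance.

**Category summaries** count significant up/down calls over a fixed
eleven-label functional vocabulary (`table1_categories()`), with a `Total`
row equal to the column sums; features missing from the category map are an
error unless a default label (normally `"Hypothetical protein"`) is
explicitly configured, so silent miscategorization cannot occur.

**Transcriptome clustering** uses 1 − Pearson correlation on log2 corrected
expression with average linkage. Neither the distance nor the linkage was
documented; this pair is a common default for expression profiles, both
knobs are visible in the result object, and experiments are ordered
lexicographically before clustering so tie-breaking is deterministic. Trees
serialize to newick via `ape`.

### Fold compression under quantile normalization

Quantile normalization equalizes whole intensity distributions. When a
large fraction of one experiment's upper tail consists of genuinely induced
features, their intensities are pulled toward the cross-array reference and
measured folds shrink. At the study's scale (tens of regulated genes among
~6000 features) the effect is small; in tiny simulated designs where the
spiked features *are* the upper tail it is visible (see the README
example). For this reason the noiseless exactness checks in the tests run
the summarization chain without the normalization step — with zero noise
and no array effects there is no distribution difference to remove — while
the noisy recovery benchmarks run the full chain including it.

## Synthetic probe data

`simulate_probe_data()` draws, for each probe, a lognormal affinity factor
shared across arrays (probes differ in brightness but consistently so —
the structure quantile normalization and per-feature medians are designed
to tolerate), multiplies true expression by affinity and by mean-1
lognormal noise, and adds a per-array additive background; null probes
carry background times noise only. A lognormal noise model was chosen
because intensities are positive and right-skewed; the measurement noise
level is not documented for these arrays, so the default
`noise_cv = 0.15` is a package choice — typical of two-channel-free
spotted-oligo replicates — and remains configurable. The default
`affinity_sdlog = 0.25` gives probe-to-probe brightness spreads of roughly
±50%, again a realism choice, not a fitted value.

The generator does **not** simulate probe sequence composition, GC bias,
scanner saturation, or spatial artifacts; passing recovery tests on this
generator therefore demonstrates correctness of the arithmetic chain and
its statistical behavior under multiplicative noise, not robustness to
those instrument effects.

A spike-in benchmark (1000 null features plus 20 features spiked 5-fold,
six probes per feature, 300 null probes, two replicate arrays per
experiment, noise CV 0.15, ten seeds) is run by both the test suite and
`scripts/acceptance.R`: the joint fold ≥ 3 / *P* ≤ 0.05 rule yields an
empirical false-positive rate well under 1% — the fold gate alone sits
~7 standard deviations from a null feature's expected log-ratio at this
noise level — with sensitivity above 95%. Baseline expressions are drawn
lognormal around 1000 units (sdlog 0.5) over a background of 100, so
corrected signals stay comfortably above the floor.

## GC-MS metabolomics

`compute_rrf()` divides each peak's response factor by the ribitol
response factor of the same sample. This cancels per-sample instrument
gain exactly (a tested invariance), which is the point of an internal
standard; the ribitol spike level is metadata only, and no absolute
intracellular concentrations are computed because cell-volume
normalization is not part of the workflow.

`anova_screen()` runs a one-way fixed-effects ANOVA per compound across
strains *within* each growth condition, because the published comparisons
contrast four strains per medium; a two-way model with condition as a
factor was not described and is not fitted. `stats::aov` supplies the
decomposition; the all-values-identical case (0/0) is mapped to *F* = 0,
*p* = 1. The *P* ≤ 0.05 screen is again uncorrected by default with a BH
option.

`excretion_timecourse()` adds one derived summary not present in the
original figures: the terminal/initial mean-RRF ratio per strain and
compound (accumulation index), which makes "metabolite X accumulates in
strain Y" assertable as a number. `fit_standard_curve()` /`quantify()` are
ordinary least squares and its inverse; signals below the blank return
negative concentrations with a `below_blank` flag instead of truncation at
zero, so averages of replicate quantifications remain unbiased.

The peak-table generator multiplies true RRF by the internal-standard
response factor and mean-1 lognormal noise (`replicate_cv = 0.1` by
default, a typical replicate-culture CV for derivatized polar
metabolites); it does not simulate retention-time drift, co-elution or
derivatization efficiency — the pipeline starts at integrated response
factors by design.

## Growth curves

`generation_time()` regresses ln(OD600) on time over the points with
0.1 ≤ OD600 ≤ 0.3 — an absolute window, as reported, not relative to the
carrying capacity — and converts the slope to g = ln 2 / b per replicate,
then reports mean ± sd across replicates. Regression over all window
points is used rather than two-point doubling because it uses the full
window and is far less sensitive to single-point noise; on noiseless
exponential data the two coincide. OD values are used as recorded
(path-length-uncorrected). At least three window points per replicate are
required, and a non-positive slope (no growth in the window) is an error,
not a negative generation time.

`detect_first_phase_end()` operationalizes "end of the first growth
phase", which the original description leaves informal. The specific
growth rate µ(t) is the central difference of rolling-median-smoothed
(window 3) ln OD; the phase end is the earliest time — after the culture
passes OD 0.1, so lag-phase wobble cannot trigger it — at which µ drops
below `min_rate_fraction = 0.25` of its running maximum for at least
`min_pause_points = 2` consecutive points. Both knobs are exposed. Each
replicate is aligned at its own detected phase end over a ±3 h window,
reproducing the overlay in which strains entering the shift at different
times are compared. A monotone exponential curve yields `detected = FALSE`
rather than a spurious time.

The growth generator's diauxic model is exponential at µ1, *exactly* flat
for the pause, then exponential at µ2 capped at the carrying capacity.
Real pauses are smooth; the flat idealization is acceptable because the
detector is only required to localize the phase end to within two sampling
intervals, which it achieves at 2% noise. The monophasic model is logistic
with carrying capacity `od_max`; setting `od_max = Inf` gives pure
exponential growth, the limit used by the closed-form checks (a logistic
curve is only exponential while OD ≪ od_max, so exact doubling-time
assertions are made in that limit). Defaults — od0 = 0.05,
µ1 = ln 2 / 2 h⁻¹, od_max = 1.5, noise CV 2%, triplicate wells — describe a
typical minimal-medium plate-reader run.

## Orchestration and reporting

`run_pipeline()` executes normalize → filter → background → expression →
DE → category summary → clustering, plus the metabolomics and growth
stages when their input files are configured, writing TSV outputs and a
JSON report. Two reporting rules keep the numbers trustworthy: every count
in the report is recomputed from the *written* output file rather than
from in-memory objects, and percentages are rounded to the nearest integer
with the raw value retained alongside. Reruns with the same configuration
are identical up to the timestamp. The exported functions,
`simulate_fixture_set()` (which writes a complete coherent input set plus
a ground-truth JSON) and `scripts/acceptance.R` are the package's
command-line surface.

## Problem sizes and numerical choices

The recovery benchmarks use 1020 features × 4 arrays × 10 seeds for the
spike-in study, 30 diauxic curves (three pause times × ten seeds) for
detection, and triplicate noiseless curves for the closed-form checks —
sizes at which every quantity stabilizes to well within the tolerances
asserted, while the whole suite runs in seconds. Seeds are explicit
arguments everywhere; no function touches the global RNG state except
through `withr::with_seed`. Ties in quantile normalization, zero-variance
groups in both test statistics, floored expression values and below-blank
concentrations all have documented, flagged behaviors rather than NaNs.

## Known limitations

- The probe generator's noise and affinity parameters are package choices;
  absolute false-positive/sensitivity numbers from the benchmark
  characterize the pipeline under those conditions, not any particular
  scanner.
- With two replicates per experiment the *t*-test has df = 2 and very low
  power; the fold ≥ 3 gate does most of the work, as it did originally.
  The pipeline reports both components so users can judge.
- The diauxic detector assumes a genuine rate collapse; a gradual shift
  between carbon sources with no pause will (correctly) not be detected.
- Hierarchical clustering of six experiments is descriptive; no bootstrap
  support values are computed.
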