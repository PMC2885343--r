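---
title: "Window-based aCGH contrast analysis: models, parameters and design choices"
author: "CNVcontrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based aCGH contrast analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

CNVcontrast compares the somatic copy-number landscapes of two patient
groups measured on probe-level aCGH arrays, and asks which recurrent
gains and losses differ in frequency between the groups and which genes
inside those regions show a concordant mRNA dosage response. This
vignette documents the statistical model behind each stage, the
parameters a user can turn, why their defaults are what they are, and
the design decisions taken where the methodology left genuine choices.

## The measurement model

A tumor/reference hybridization yields one normalized log2 ratio per
probe: 0 for balanced copy number, positive under gain, negative under
loss. Probe-level noise on oligo platforms is large relative to
single-copy effects, so the analysis never interprets single probes.
Instead, probes are averaged in fixed windows of `probesPerWindow = 10`
consecutive probes — roughly 60 kb at the ~6 kb spacing of a 385k-probe
whole-genome design. Averaging 10 probes shrinks the noise standard
deviation by √10 and makes the per-window false-positive behavior easy
to calibrate (below). Windows never span chromosome boundaries; the last
window of a chromosome keeps however many probes remain, preserving the
partition of probes into windows.

A window mean above `gainCut` (+0.1 by default) is called `GAIN`,
strictly below `lossCut` (−0.1) `LOSS`, otherwise `NORMAL`. Both
comparisons are strict: a mean exactly at a cut stays `NORMAL`. This
boundary convention is deliberate — calibrated cuts are empirical order
statistics of a control, and strict inequalities are what make the
control false-positive guarantee (below) hold exactly.

### Masking

Four classes of territory are excluded from all downstream statistics,
because ratio behavior there reflects technique rather than tumor
biology: a telomeric pad at each chromosome end (`telomerePad`,
default 120 kb ≈ two windows; the appropriate width is
platform-dependent, so it is a parameter rather than a constant),
centromeres, the whole p-arm of acrocentric chromosomes, and the sex
chromosomes (tumor-vs-reference ratios there track patient sex, not
somatic state). A window intersecting any mask is wholly `MASKED` in
every sample — partial windows are not rescued, mirroring the practice
of discarding centromere-spanning calls outright.

### Threshold calibration on a self-control

A self-self hybridization (the same reference pool in both channels)
contains no true copy-number signal, so the fraction of its unmasked
autosomal window means beyond the cuts *is* the per-window
false-positive rate. `calibrateThresholds()` inverts this: given target
rates (defaults 0.005 for gains, 0.007 for losses — an asymmetry that
real controls show), it returns the order statistics
`x[ceiling(n(1-t_g))]` and `x[floor(n·t_l)+1]` of the control means.
With the strict call inequalities these guarantee
`empiricalFpr(calibrate(x)) <= targets` on the calibration control for
any distribution — a property `stats::quantile()`'s interpolating types
do not provide, which is why the order statistics are taken explicitly.
A control of at least ~1000 unmasked windows is recommended (a warning
fires below that); at 50,000 windows the calibrated gain cut reproduces
the distributional quantile to within a few thousandths of a log2 unit.

The female-vs-male control plays the opposite role: a hybridization with
a known, genome-wide true signal. With the sex-chromosome mask lifted
for this check, essentially every chrX window must be called `GAIN` and
every chrY window `LOSS`; anything less indicates thresholds or
normalization problems.

## Aberration segments, counts and breakpoints

Maximal runs of identical non-`NORMAL` state form aberration segments.
By default a `MASKED` gap flanked by the same state is bridged
(`bridgeMasked = TRUE`): a gain running from p-arm to q-arm across the
centromere is one biological event, not two. Bridging never joins
opposite states.

Counting follows the whole/interior rule: every segment is one
chromosomal aberration; a segment covering all unmasked windows of its
chromosome adds 0 breakpoints, an interior segment 2. The rule is
silent about a segment touching exactly one chromosome end; we count 1,
the unique interpolation consistent with "one breakpoint per internal
state boundary", and flag it as our choice. "Touching an end" is
evaluated against unmasked windows, since the telomere pad makes the
literal first and last windows unreachable.

Genome-fraction aberrant and percent-normal are computed over unmasked
windows only and sum to one exactly; both bp-weighted (default) and
window-count weighting are available because the published percentages
do not state their denominator. Replicate concordance R² is the squared
Pearson correlation over all probes in windows where at least one of
the two replicates is non-`NORMAL` — computed on probes, not window
means, so it reflects the raw measurement agreement. Group differences
in the per-sample counts use the Mann–Whitney test by default (the
counts are skewed, and no specific test is canonical here); a t-test is
available by option.

## Differential-frequency mapping

For each unmasked window and each direction separately, the carrier
table (gain vs no-gain, loss vs no-loss; a window can in principle be
significant in both directions) is tested with a two-sided Fisher exact
test. `fisherExact2x2()` is implemented in-package: for tables whose
binomial coefficients are exactly representable in doubles (row sums up
to ~50, far beyond a 23-vs-17 cohort) the two-sided tail is accumulated
as exact integer counts, so the "sum of probabilities ≤ observed" rule
needs no floating-point tie tolerance at all; larger tables fall back
to log-space with the conventional 1e-7 relative guard. The test suite
checks the implementation against an independent Pascal-triangle
enumeration oracle over every table with group sizes up to 25, and
against `stats::fisher.test`.

Windows with p < `alpha` (0.05) merge into maximal same-direction runs;
a gap consisting solely of masked windows is crossed (consistent with
segment bridging), and any region whose span then overlaps a centromere
is discarded. No multiple-testing correction is applied by default —
the window tests are heavily correlated along the genome and the
published convention for this analysis reports raw averaged p-values;
`stats::p.adjust()` can be applied to the window table by users who
want FDR control. A region's `avg_p` is the unweighted arithmetic mean
of its member windows' p-values, the most direct reading of an
"average p" summary.

### The smallest region of overlap

Within a region, the SRO is the interval where the recurrent aberration
stacks up: formally, among all contiguous window sub-intervals we
maximize the number of enriched-group samples aberrant across the whole
sub-interval, and among ties on that count return the maximal
(largest-extent, then leftmost) sub-interval. The maximal-extent
tie-break matters: the SRO is the *intersection* of the carriers'
aberrations — "smallest" relative to each carrier's own event — and
when carriers are uniform across the region any sub-window would tie on
the count, so a smallest-extent rule would degenerate to a single
window.

One robustness parameter enters here: a sample counts as a carrier of a
sub-interval only if its aberration spans at least `minRun = 3`
consecutive member windows. At the calibrated false-positive rates a
large region contains several isolated noise-called windows among
non-carrier samples; without the guard, one such window would add a
spurious extra carrier and pull the SRO onto itself. Requiring a few
consecutive windows is the standard aCGH defense against isolated
threshold crossings; `minRun = 1` restores the unfiltered search. The
search itself is an exhaustive O(k²) scan, cross-checked in the tests
against an independently implemented brute-force oracle.

## Expression integration

Each gene inherits the state of the windows it overlaps: unanimous
unmasked windows decide directly; on disagreement the window containing
the gene midpoint decides (documented choice — the mapping of a
boundary-spanning gene is not otherwise defined); all-masked territory
yields `MASKED`.

The dosage statistic is a ratio of medians: per gene and per direction,
median expression of the carrier samples over median expression of the
copy-number-normal samples, pooled across both patient groups (the
statistic describes dosage response, not group difference). Ratios are
computed on the **positive linear** expression scale. This is the one
place where the conventional description ("quantile-normalized,
gene-median-centered data") cannot be taken literally: centered log
values are zero-median by construction and can be negative, making a
ratio of medians ill-defined; the linear scale is the only
self-consistent reading, and the package stores expression linearly and
derives the centered log2 view (`centeredLogExpr()`) for testing only.
Concordance is declared at ratio ≥ 1.5 for gains (inclusive — the
cutoff's phrasing does not exclude equality) and strictly below 0.75
for losses ("below" is unambiguous); both cutoffs are arguments.

Genes are then filtered to those intersecting a significant region of
matching direction, and the early-vs-late difference of each such
gene's centered log2 expression is tested with a two-sided
pooled-variance t-test (the classic "independent samples t-test";
Welch by option). The shortlist is
`concordant AND in-region AND p < alpha`, sorted by increasing p and
then by ratio extremity, mirroring the conventional presentation of
such candidate lists.

## The synthetic cohort generator

The generator is first-class, tested code: it is how the pipeline's
operating characteristics are demonstrated without access to patient
arrays. Its defaults encode the study conditions the package targets:

* **Cohort**: 23 "early" vs 17 "late" samples.
* **Probe map**: ~6 kb mean spacing with seeded jitter; a 2.31 Gb
  masked-autosome genome at this spacing reproduces a ~385k-probe
  design. The bundled desk-scale genome (8 × 80 Mb autosomes + XY,
  ~125k probes) keeps the full pipeline under a minute.
* **Noise**: per-probe Gaussian log2 noise with
  `noiseSd = 0.1·√10 / qnorm(0.995) ≈ 0.123`, chosen so that 10-probe
  window means put the ±0.1 thresholds exactly at a 0.005 per-window
  false-positive rate — the calibration regime of a real self-control.
* **Event magnitudes**: `log2(2.5/2) ≈ +0.32` for single-copy gains and
  `log2(1.5/2) ≈ −0.42` for single-copy losses at ~50% tumor-cell
  content, a typical purity for colorectal resections. A closed-form
  consequence worth recording: with these magnitudes and noise, the
  replicate R² of two hybridizations of the same tumor falls in the
  0.7–0.9 band reported for re-hybridized samples on this platform
  (signal variance of the selected aberrant probes over itself plus
  twice the probe noise variance, squared).
* **Penetrance**: shared backbone events at 60% in both groups;
  early-specific events at 14/23 vs 2/17. Carrier counts are exact
  (`round(p·n)`, with the carrier identities seeded-random) so planted
  contrasts reproduce printed carrier tables exactly — the per-window
  Fisher p of a planted specific locus is 0.003 deterministically.
* **Expression**: coupled genes multiply (gains) or divide (losses)
  their expectation by `dosageEffect`; decoupled genes ignore copy
  number; log-normal noise with log2 sd 0.3. The default
  `dosageEffect = 2.2` was fixed by a design-time power analysis of the
  group t-test under the 14/23-vs-2/17 carrier mixture (per-gene power
  ≈ 0.97 at this effect and noise, vs ≈ 0.86 at 1.8): recovery
  experiments on the shortlist are meant to be adequately powered, and
  the within-group variance contributed by the carrier mixture — which
  caps attainable power at this penetrance — is intrinsic, not a knob.

What the generator does **not** emulate, and what passing recovery
tests therefore do not establish for real data: GC/wave artifacts and
other spatially correlated noise, tumor purity variation between
samples and subclonal events (magnitudes are fixed per event),
segmentation-level breakpoint uncertainty, probe-specific response, and
microsatellite-instable biology (the targeted design excludes MSI-H
tumors). Real-data thresholds should always be re-calibrated on the
platform's own self-control.

## Numerical and reproducibility choices

* Coordinates are 1-based closed inside the package (GRanges
  convention); BED I/O converts to 0-based half-open, SEG output is
  1-based inclusive, and the genome-spec TSV keeps 0-based half-open
  centromere columns.
* All writers format floats at 6 significant digits and are
  byte-deterministic; the pipeline manifest records MD5 checksums of
  every stage output, and rerunning with the same seed reproduces them
  exactly.
* Every stochastic component draws from a substream derived
  deterministically from one master seed (Lehmer-style mixing kept
  inside 32-bit integer range), so components can be regenerated
  independently; RNG state of the caller is saved and restored.
* Undefined window means (all probes missing) are called `NORMAL` with
  a warning — the conservative choice, since `MASKED` would silently
  change denominators.
* An empty-margin Fisher table returns p = 1; a constant metric in both
  groups returns p = 1 with a warning rather than an error, so batch
  runs survive degenerate genes.
* Desk-scale problem sizes used by the test-suite demonstrations: the
  default study genome above for recovery and integration; a 10 × 310 Mb
  genome (~51k windows) for calibration properties; exhaustive Fisher
  verification over all tables with group sizes ≤ 25. These sizes were
  chosen so each property is measured at, or comfortably beyond, the
  sample sizes of the targeted study design.

## Known limitations

* Window averaging is not segmentation: breakpoints are quantized to
  window boundaries (~60 kb), and events shorter than about half a
  window are diluted below the thresholds.
* The per-window Fisher tests are correlated along the genome; region
  counts under the null are controlled empirically (label-permutation
  checks in the test suite) rather than analytically.
* The integration shortlist inherits the t-test's sensitivity to the
  carrier mixture: at 14/23 penetrance and realistic expression noise,
  per-gene power cannot exceed ~0.95 regardless of effect size, so
  occasional misses of a true dosage-coupled gene are expected
  behavior, not bugs.
* The midpoint rule for boundary-spanning genes and the 1-breakpoint
  rule for arm-terminal segments are documented conventions; alternate
  readings would shift per-gene states and breakpoint counts slightly.
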