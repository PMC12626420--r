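---
title: "Methods: behavioral and whole-brain phenotyping for microexon mutant screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral and whole-brain phenotyping for microexon mutant screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mexscreen)
```

mexscreen implements the analysis side of a high-throughput phenotyping
screen of larval zebrafish mutant lines: behavioral profiling from
delta-pixel tracking, whole-brain voxel-wise activity and structure
mapping with an empirically calibrated significance threshold, and a
set of microexon sequence and RT-PCR utilities. This vignette explains
the models and procedures, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The screening problem

Mutant lines are raised as sibling clutches containing wild-type
(`+/+`), heterozygous (`+/-`) and homozygous (`-/-`) larvae. Each
larva is tracked in a 96-well plate over several days; the camera
reports one aggregate movement magnitude per frame (the *delta-pixel*
count, the number of changed pixels) plus a centroid position.
Stimulus responses (dark flashes, light flashes, acoustic taps of
several intensities and a habituation block) are captured as separate
1-s high-speed movies at 285 frames/s. Separately, fixed brains are
stained for phospho-Erk / total-Erk (an activity proxy) and registered
to a reference brain, giving one scalar volume per fish; the
registration deformation's Jacobian determinant gives a second,
structural channel. The package consumes these pre-registered volumes;
registration itself is out of scope.

## Behavioral profiling

### Bout detection

Larval swimming is episodic, so the per-second delta-pixel trace is
segmented into *bouts*: maximal runs of samples with
`dpix > threshold`. Runs separated by gaps shorter than `merge_gap_s`
are bridged (the bridged samples stay part of the bout), and merged
runs shorter than `min_duration_s` are discarded. Defaults are
`threshold = 0` (appropriate for denoised or simulated input — a real
tracker noise floor is passed explicitly), `merge_gap_s = 0.2` s, and
`min_duration_s = 0`. With fully permissive parameters the summed
bout movement equals the summed trace, a conservation property the
tests exercise.

### Measures and the naming grammar

Baseline behavior is summarized per *epoch* (the whole recording,
`combo`, plus one epoch per light-cycle segment: `day0`, `day0night`,
...) in bins of `bin_s = 3600` s. Bouts belong to the bin containing
their start; a trailing partial bin is dropped, which keeps per-bin
counts additive over the epoch. Per epoch the package emits
frequency measures (`numberofbouts`, `activeseconds`, as per-bin
means), magnitude measures (`boutcumulativemovement`, `boutvelocity`,
means over bouts), and a location measure (`boutcenterfraction`, the
bout-time-weighted fraction of bout samples inside the well center).
The well is the unit circle and "center" means radius at most 0.5 —
a center/edge preference measure needs *some* boundary, and half the
radius (a quarter of the area) is the fixed, documented choice.

Stimulus measures are computed per stimulus subset (for example, the
dark flashes of block 1, or the strong acoustic stimuli preceding a
habituation block): `responsefrequency` (fraction of events whose
burst contains a supra-threshold sample), `responselatency` (mean
onset time over responders only, in ms, with onset defined as the
first supra-threshold sample — the only unambiguous landmark), and
`responsemagnitude` (mean cumulative burst dpix over responders).
Averaging latency over responders only keeps frequency and latency
orthogonal; with no responders the latency is missing rather than
imputed.

Columns follow the screen's naming grammar,
`epoch_measure[_suffix]` — e.g. `day0night_boutcenterfraction_3600`
or `day5dpfhab1pre_responsefrequency_1_a1f1000d5p` — with the epoch
and measure components underscore-free so parsing is an exact
inverse (`parse_measure_name()`).

### Group comparison and SSMD

Each measure is compared between genotype groups (homozygous vs
wild-type siblings by default; heterozygous contrasts use the same
machinery) with a two-group Kruskal-Wallis test on tie-corrected
midranks. For pooled samples of at most 10 the p-value is computed by
exhaustive enumeration of group assignments, which makes the null
exact at small n; larger samples use the chi-square approximation.
The per-measure level is `alpha = 0.05` with no multiple-testing
correction: in this screen design, replication across two biological
replicates — displayed side by side — is the guard against false
positives, and a correction toggle would only hide that structure.

Effect sizes are strictly standardized mean differences,

$$\mathrm{SSMD} = \frac{\mu_1 - \mu_2}{\sqrt{\sigma_1^2 + \sigma_2^2}},$$

with sample variances, signed so positive means the mutant group is
increased. Category summaries (`summarize_categories()`) merge
related measures (all frequency measures, and so on) and report, per
category and sign, the percent of significant measures and the mean
SSMD of those significant measures — the size and color of a bubble
in a screen summary plot. The percent uses the category's *full*
measure count as denominator (not only testable measures); the
alternative is defensible but the full count keeps bubbles comparable
across mutants with different missingness.

## Whole-brain voxel mapping

### The statistic

Groups of registered stacks are compared voxel-wise with a two-sided
Mann-Whitney rank-sum statistic expressed as a tie-corrected normal
deviate Z, signed so positive means the first group is stochastically
larger. The statistic is nonparametric, which matters because
activity ratios are not Gaussian and sample sizes are 10-30 per
group. All-tied voxels get Z = 0. The displayed effect magnitude is
the difference of group medians — robust, and sign-consistent with
the rank statistic.

### Empirical significance calibration

Rather than a parametric FDR, the screen's rule is operational: pick
the |Z| threshold at which a stated fraction — 0.05% — of *control*
voxels would be called significant. `calibrate_threshold()` realizes
this by repeatedly splitting the control stacks into random halves,
computing control-vs-control |Z| maps, pooling all values, and taking
the smallest pooled value whose at-or-above fraction does not exceed
the target. This is an empirical `1 - f` quantile with a
left-continuity convention chosen deliberately: the rank-sum null is
discrete, so a plain interpolated quantile can overshoot the target
by the width of one probability atom (about 45% at 10-vs-10 splits),
whereas the chosen convention flags the largest attainable fraction
*at or below* the target. The realized fraction is reported on a
held-out split.

Because the rank statistic is distribution-free under the null, the
pooled splits sample the exact discrete null regardless of the
control data's distribution; more splits therefore only reduce the
Monte-Carlo error of locating the right atom. The default is
`n_splits = 20`; the calibration analyses here use 1000-2000 splits
because the target atom's tail probability (4.87e-4 at 10-vs-10)
sits within 3% of the 5e-4 target and a precise pooled estimate is
needed to select it reliably. Pooling stays cheap at that split
count: midranks are computed once per control pool, each split is a
column sum, and only pooled values above a generous cutoff (50x the
target tail) are retained, which is exact because midrank sums are
integer multiples of 0.5 and hence bitwise reproducible.
Whether the original screen calibrated one global
threshold or one per comparison is not stated; the package calibrates
per comparison, and "control pixels" is read as voxels of the 3D
stack.

### Maps, regions, projections

`significance_map()` zeroes sub-threshold voxels and keeps the signed
median-difference elsewhere (increase/decrease = the green/magenta
channels of a mapping figure); no spatial smoothing or cluster-size
filtering is applied by default, since the stated rule is per-voxel.
`region_quantify()` sums positive and |negative| signal per atlas
region and divides by region size, so a uniform effect yields the
same summary whatever the region's volume. `total_signal()` sums
|signal| over all voxels, counting increases and decreases as one
comparison, and `sum_of_slices()` produces signed z- and x-axis
projections. The structure channel (Jacobian determinant volumes)
flows through identical operations; a planted determinant decrease
surfaces as negative (decreased-size) signal.

## Microexon sequence utilities

A microexon is an exon of 3-30 nucleotides (1-10 amino acids);
`microexon_length_filter()` applies exactly that closed interval.
Conservation is quantified by global alignment percent identity
(match 1, mismatch 0, linear gap -1; identity = matches / alignment
columns — the simplest defensible scheme for 1-10 aa peptides, and
documented rather than implied), and by `identity_ratio()`, the
microexon identity divided by the full-protein identity, which
exceeds 1 when the microexon is the more conserved part.

The canonical Srrm4-regulated layout places a UGC repeat and a UC
repeat / polypyrimidine tract directly upstream of the exon.
`classify_upstream_layout()` scans the last `window_nt = 100` nt for
two features: at least `min_ugc = 2` UGC occurrences within the
proximal 30 nt, and any 10-nt run with pyrimidine fraction at least
0.75. Both features = canonical, one = partial, none = noncanonical.
The published counts distinguishing canonical from near-canonical
layouts rest on qualitative criteria; these thresholds are explicit,
configurable stand-ins, and the classifier is by construction
invariant to sequence outside the scan window and monotone in UGC
content. DNA input is transcribed (T to U) before scanning.

RT-PCR inclusion is `included / (included + skipped)` band intensity;
qRT-PCR relative expression uses the delta-delta-Ct rule
`2^-(dCt - mean(control dCt))`, which normalizes the control group to
1 by construction. Developmental inclusion profiles are clustered
with average linkage on Euclidean distances (the defaults of the
common clustered-heatmap tools); the dendrogram is also serialized as
Newick.

## The synthetic cohort generator

Every stage is testable without external data because the generator
plants known effects:

* **Bout process** — alternating exponential on/off durations (off
  mean 9 s by day, 29 s by night on the 14 h/10 h cycle; on mean
  2 s) with gamma per-frame movement (shape 3, scale 10) while
  active. A planted bout-rate multiplier divides the off mean, so
  expected bouts/hour scale almost proportionally; a magnitude
  multiplier scales the gamma scale. This is the simplest process
  that separates frequency from magnitude the way the measure
  taxonomy does.
* **Well position** — per-sample: with probability `p_center = 0.25`
  (the area fraction of the half-radius disk) uniform in the center
  disk, else uniform in the annulus; a planted center shift moves
  that probability.
* **Stimulus bursts** — per event, a Bernoulli response with
  kind-specific probability (e.g. 0.7 for dark flashes, 0.3 for weak
  acoustic), a kind-specific onset latency (slow for visual, fast
  for acoustic) and a ~100 ms gamma-distributed movement burst;
  planted deltas shift probability, latency, and magnitude for
  homozygous mutants.
* **Brain stacks** — baseline 1 plus i.i.d. Gaussian noise (sd 1);
  mutants receive an additive delta inside one atlas region
  (activity) or a multiplicative factor (structure). The synthetic
  atlas is a set of compact labeled blobs in a background-0 volume.

All randomness flows through one integer seed per config, and a fixed
seed reproduces every artifact byte-for-byte. Default cohort sizes
(20 per genotype) match typical screen group sizes (15-29 per group
per replicate).

What the generator does *not* emulate — and hence what green tests do
not certify about real data: video-level tracking artifacts, real
locomotor kinematics (O-bend/C-bend structure, refractory periods),
spatially correlated staining noise and registration error, circadian
drift beyond a square-wave day/night rate switch, and true biological
variance structure between clutches. Parameter-recovery results on
synthetic cohorts bound what the pipeline can do under its own
assumptions, not what a particular screen will detect.

## Problem sizes and numerical choices

The simulation-based analyses use desk-scale problem sizes chosen
once: 64 x 64 x 16-voxel stacks with 20 controls for calibration
checks (1024-2048 pooled splits, 50 held-out null cohorts), 32 x 32 x 8
stacks with 10 fish per group over 50 seeds for planted-region
recovery, and 1-hour baseline recordings with 20 larvae per genotype
over 100 seeds for behavioral effect recovery. Ties in the rank
statistic are handled by midranks with the standard tie-corrected
variance; zero-variance voxels map to Z = 0; SSMD with both group
variances zero is flagged missing rather than forced to a value; and
hierarchical clustering inherits `stats::hclust`'s deterministic
agglomeration so orderings are reproducible across runs.

## Known limitations

The response-onset rule and subset-membership conventions of the
original tracker are not replicated bit-for-bit (they live in
tool-specific code, not in any publication); the measure grammar and
subset machinery are general enough to express them. The NRRD
reader/writer covers the attached-header raw-encoding subset the
pipeline itself writes, not the full format. Exact Kruskal-Wallis
p-values are enumerated only for pooled n of at most 10; beyond that
the chi-square approximation is standard but approximate. The
calibration's discrete-atom analysis assumes exchangeable control
stacks; strong spatial correlation would widen the Monte-Carlo error
of the realized fraction, though not bias the distribution-free
threshold.
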