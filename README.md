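# mexscreen

Analysis toolkit for high-throughput phenotyping screens of larval
zebrafish mutant lines — the kind of screen used to characterize
mutants lacking conserved, neuronally included **microexons** (exons
of 3–30 nt / 1–10 aa). It is aimed at labs running multi-line
behavioral + whole-brain imaging screens who need the downstream
analysis to be reusable, testable, and runnable without the original
raw data.

Three analysis stages, plus a synthetic-cohort generator that makes
every stage testable end to end:

1. **Behavioral profiling.** Delta-pixel traces are segmented into
   movement bouts; baseline *frequency*, *magnitude*, and *location*
   measures are computed per epoch and hourly bin, and
   stimulus-response *frequency* / *latency* / *magnitude* measures
   per stimulus subset from 285 fps burst recordings. Genotype groups
   are compared per measure with a Kruskal–Wallis test (exact by
   enumeration at small n), and effects summarized by the strictly
   standardized mean difference

   SSMD = (μ₁ − μ₂) / √(σ₁² + σ₂²),

   rolled up into category-level "bubble" tables (percent significant,
   mean SSMD of significant measures, split by sign).

2. **Whole-brain mapping.** Registered per-fish activity (pErk/tErk)
   or structure (deformation-determinant) volumes are compared
   voxel-wise with a tie-corrected rank-sum Z. The significance
   threshold is **calibrated empirically so that 0.05% of control
   voxels would be called significant** (pooled random half-splits of
   control stacks), yielding signed significance maps, sum-of-slices
   projections, atlas-region summaries (signal summed / region size),
   and total-signal comparisons.

3. **Microexon sequence utilities.** The 3–30 nt length filter,
   mouse–zebrafish peptide percent identity (global alignment) and
   identity ratios, classification of the upstream splice-regulatory
   layout (UGC repeat + polypyrimidine tract ⇒ canonical),
   RT-PCR inclusion fractions, ΔΔCt relative expression, and
   average-linkage clustering of developmental inclusion profiles.

## Worked example

Simulate a sibling cohort in which homozygous mutants start bouts 1.8×
more often, extract the measure matrix, and summarize:

```r
library(mexscreen)

cfg <- sim_config(n_per_genotype = 15, duration_s = 3600, seed = 7,
                  effect_spec = list(bout_rate = 1.8))
coh <- simulate_behavior_cohort(cfg, default_schedule(3600))
mm  <- build_measure_matrix(coh)
mm
#> Measure matrix: 30 larvae x 28 measures ( frequency: 10, latency: 6, location: 2, magnitude: 10 )
#>   2 missing cells

res <- compare_all_measures(mm, coh$genotypes)   # -/- vs +/+
head(res[, c("measure", "p_value", "ssmd", "significant")], 5)
#>                             measure      p_value        ssmd significant
#> 1          combo_numberofbouts_3600 2.990346e-06  7.79673845        TRUE
#> 2          combo_activeseconds_3600 3.066978e-06  5.53010408        TRUE
#> 3 combo_boutcumulativemovement_3600 1.198443e-01  0.38426540       FALSE
#> 4           combo_boutvelocity_3600 6.935503e-01 -0.05819898       FALSE
#> 5     combo_boutcenterfraction_3600 6.041263e-01 -0.29674720       FALSE

summarize_categories(res)
#>    category direction percent_significant mean_ssmd n_measures n_significant
#> 1 frequency increased                  50  5.454359         10             5
```

The planted frequency effect is recovered as an increased-sign
frequency bubble (5 of the 10 frequency measures significant, mean
SSMD +5.5), while magnitude and location categories stay quiet — the
two bout-frequency columns (`numberofbouts`, `activeseconds`) drive
the call, exactly as designed.

The brain channel works the same way: `make_atlas()` +
`simulate_brain_cohort()` give stacks with a planted regional delta;
`voxel_zmap()`, `calibrate_threshold()`, `significance_map()` and
`region_quantify()` recover it. `run_pipeline()` chains the stages
from a single YAML/list config into a directory of TSV/JSON/NRRD
artifacts with provenance, and `inst/scripts/mexscreen-run.R` wraps it
for shell use.

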