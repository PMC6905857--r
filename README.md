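# ribospike

Spike-in normalized ribosome profiling of stored, transcriptionally silent
cells — with a mature *Drosophila* oocyte aging experiment as the model
design.

## The problem

Mature stage 14 *Drosophila* oocytes are transcriptionally inactive: they
persist for days to weeks on stored mRNAs, and their capacity to support
development decays reproducibly with storage time. Standard RNA-seq and
Ribo-seq quantification is *compositional* — TPMs sum to a million in every
library — so a genuine, global decline in translation is invisible unless an
absolute anchor is added. The design this package implements anchors every
sample with a fixed mass of lysate from a diverged sister species
(*D. pseudoobscura* against *D. melanogaster*): because the spike-in amount
is constant, the ratio of focal-species to spike-species reads tracks
absolute, between-sample changes in the focal signal.

`ribospike` provides the complete analysis path for this design, plus a
synthetic two-species data generator with full ground truth so the whole
pipeline is testable without any sequencing data:

1. **Cross-species read disambiguation.** All 30-mers of the combined
   focal + spike coding sequences are indexed; a read matching exactly one
   (species, gene) pair is uniquely attributable, everything else is
   discarded — the unique-mapping filter of a combined-reference alignment,
   made exact. At ~12% per-site divergence the fraction of distinguishable
   30-nt windows is `1 − (1 − p)^30 ≈ 0.98`.
2. **Spike-in scale factors.** Per sample, `ratio = focal / spike` unique
   reads; `scale factor = ratio / mean(reference ratios)`. Footprint TPMs
   multiplied by these factors become absolute translation levels; the same
   arithmetic on the mRNA assay is the control that total mRNA stays flat.
3. **Translational efficiency.**
   `TE_g = (adjusted footprint TPM_g + c) / (mRNA TPM_g + c)` with a
   pseudocount `c` (default 1 TPM), per gene and condition.
4. **Differential translation.** Two-sided Student *t*-test on
   log2-transformed replicate values, BH-adjusted q-values, volcano-ready
   output; preferential-translation ("pilot light") classification of genes
   translated more highly in arrested oocytes than in early embryos.
5. **Viability decay.** Hatch rate vs storage day fitted as a logistic
   decay `h(t) = h0 / (1 + exp(slope · (t − t50)))` by binomially weighted
   Levenberg–Marquardt least squares; `t50` is the storage half-life.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` / `augment()` on fitted objects, `autoplot()` on result types.

## Worked example

Simulate the full study design (3 timepoints × 3 replicates × 2 assays,
2% spike-in, true bulk translation declining 1.0 → 0.595 → 0.427) and run
the pipeline:

```r
library(ribospike)

cfg <- sim_config(n_genes = 100, reads_per_sample = 50000, seed = 42)
run_simulation(cfg, "simdir")

res <- run_pipeline(pipeline_config(
  "simdir/focal.fa", "simdir/spike.fa", "simdir/samples.csv",
  out_dir = "simdir/out", reference_timepoint = "day2", verbose = FALSE
))
res$bulk_translation
#> # A tibble: 3 × 4
#>   timepoint bulk_translation      sd n_replicates
#>   <chr>                <dbl>   <dbl>        <int>
#> 1 day12                0.419 0.00421            3
#> 2 day2                 1     0.0134             3
#> 3 day8                 0.593 0.00743            3
```

The estimated bulk translation levels recover the generating factors: day-8
translation is at ~59% and day-12 at ~42% of the day-2 level, read straight
off the focal:spike ratios. The differential table reflects the global
decline (99 of 100 genes called down at p < 0.01 between day 12 and day 2
in this run; `autoplot(res$differential)` draws the volcano).

Fitting a decay curve to simulated hatch counts (200 eggs/day, true
`t50` = 12):

```r
d <- sim_hatch_data(0.95, 0.8, t50 = 12, days = 1:21, n_eggs = 200, seed = 42)
fit <- fit_decay_curve(d)
tidy(fit)
#> # A tibble: 3 × 5
#>   term  estimate std.error statistic  p.value
#>   <chr>    <dbl>     <dbl>     <dbl>    <dbl>
#> 1 h0       0.944   0.00530     178.  1.14e-30
#> 2 slope    0.804   0.0252       31.9 2.69e-17
#> 3 t50     11.9     0.0454      263.  1.03e-33
```

`h0` is the fresh-oocyte hatch plateau, `slope` the decay steepness per
day, and `t50` the storage duration at which hatching halves — recovered
here to within a tenth of a day.

A thin command-line wrapper over the same functions ships in
`inst/scripts/ribospike.R` (`simulate`, `pipeline`, `agingfit`
subcommands).

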