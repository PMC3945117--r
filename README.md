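# rhythmochip

Around-the-clock ChIP-seq analysis: block-based peak calling against a
matched input, cosinor (harmonic-regression) rhythmicity estimation,
temporal-profile clustering with circular phase statistics, and
matched-background empirical motif enrichment — plus a ground-truthed
synthetic-data generator that exercises the whole pipeline.

## The problem

A transcription factor is immunoprecipitated from the same tissue every
4 h across a day (seven libraries, ZT02–ZT26, each with an input
control). The questions: where are the binding sites, when during the
day is each site occupied, how do the binding and target-expression
phases distribute on the 24-h circle, and are known motifs enriched
under the peaks beyond what matched random regions show?

The core model for each peak's (or gene's) time course is the cosinor

x(t) = b0 + b1 · cos(b3 + 2πt/24),

with mean b0, amplitude b1 ≥ 0, peak time (−b3 mod 2π)·24/2π, an F-test
amplitude p-value against the constant model, and a delta-method phase
confidence interval. A genotype extension adds interaction terms
(b0_gt, b1_gt, b3_gt) and additive batch offsets (b4, b5) for wild-type
vs clock-deficient comparisons.

Peak calling tiles the genome into 500-nt blocks (twice, offset by half
a block), keeps blocks with ≥40 ChIP tags at some time point, quantile
normalizes log2(x+1) counts (ChIP and input as separate groups), selects
blocks with normalized log2 ChIP − input > 2 (≥4-fold) at ≥1 time
point, merges the two tilings, and refines each region's borders until
the shortest interval still holding ≥75% of the region's reads remains.

## Worked example

```r
library(rhythmochip)

# the strand-shift rule on the seven library fragment sizes (read 80 nt)
compute_shift(c(190, 184, 204, 199, 202, 208, 176), 80)
#> [1] 55 52 62 60 61 64 48

# a small synthetic world with 8 planted rhythmic sites
cfg <- sim_config(seed = 3, chrom_lengths = c(chr1 = 2e5, chrBg = 1e5),
                  n_sites = 8, depth = 8e4, n_genes = 80)
fx  <- simulate_fixture(cfg)
res <- run_pipeline(fx$chip, fx$input, run_config(seed = 3, k_clusters = 2))

res$peaks[1:3]
#>           id  chrom start   end raw_start raw_end
#> 1: peak_0001   chr1 45162 45375     45000   45500
#> 2: peak_0002   chr1 68562 68775     68500   69000
#> 3: peak_0003   chr1 85412 85625     85250   85750

round(res$fits$phase_hours, 2)      # fitted binding peak times (h)
#> [1] 18.30 13.15 15.37 16.98 12.63 17.17 17.70

sum(res$fits$amplitude_p < 0.1)     # rhythmic at the P<0.1 operating point
#> [1] 6

shortest_phase_interval(res$fits[res$fits$amplitude_p < 0.1]$phase_hours, 0.5)
#> phase interval [ZT16.98, ZT17.70], length 0.72 h, coverage 50%

expr <- rowMeans(fx$expression$mat)
motif_enrichment(fx$genome, res$peaks, fx$truth$genes, expr,
                 motif_model("SRE", consensus = "ATCACCCCAC"),
                 n_groups = 1000, seed = 3)
#> motif enrichment: observed 3 vs 1000 matched groups (null max 2), empirical p <0.001
```

Seven of the eight planted sites are called (the eighth is a weak,
6-fold site at this reduced scale), their fitted peak times cluster in
the ZT13–18 window the generator planted, half of the rhythmic peaks
fall in a 0.72-h arc, and the embedded sterol-regulatory-element motif
is enriched beyond all 1000 matched random region groups.

The command line mirrors the same stages:

```sh
Rscript inst/cli/rhythmochip.R simulate --seed 1 --out fixtures/
Rscript inst/cli/rhythmochip.R run --fixtures fixtures/ --out results/
```

## Layout

- `R/` — tag processing, peak calling, rhythm fitting, motifs,
  annotation, simulation, pipeline, CLI
- `tests/testthat/` — unit, property (oracle-equivalence) and
  acceptance suites
- `vignettes/rhythmochip-methods.Rmd` — models, parameter rationale,
  numerical choices, known limitations
- `scripts/acceptance.R` — the acceptance report
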