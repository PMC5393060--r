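# maccr — nucleosome accessibility and occupancy from MNase titration series

Single-concentration MNase-seq conflates two distinct properties of
chromatin: **how many nucleosomes** sit at a locus (occupancy) and **how
easily MNase releases them** (accessibility). Digesting the same chromatin
at a series of increasing MNase concentrations separates the two:
accessible nucleosomes are released preferentially by gentle digestion and
over-digested away at high enzyme levels, while inaccessible nucleosomes
only appear at deep digestion. `maccr` implements this titration analysis
for paired-end fragment data, for chromatin biologists who want both
quantities from one experiment.

## The model

For each non-overlapping genomic bin (200 bp by default), the
library-normalized fragment frequency *f<sub>ℓ</sub>* is computed at each
titration level ℓ = 1…4. Two per-bin summary statistics are derived:

- **MACC (accessibility)** — the ordinary least-squares slope of
  *f<sub>ℓ</sub>* on ℓ, corrected for GC content by subtracting a locally
  weighted (lowess) trend of slope on bin GC fraction, then sign-flipped:

  MACC = −( slope(f<sub>ℓ</sub> ~ ℓ) − t(GC) ),&emsp;
  slope = (−3f₁ − f₂ + f₃ + 3f₄)/10

  Accessible chromatin loses signal as digestion deepens (negative raw
  slope), so the flip makes accessible bins positive.

- **Occupancy** — the titration-averaged frequency mean(f₁…f₄), optionally
  ChIP/input or input-subtracted; or per-bp fragment coverage of a
  pooled-digest library ("traditional" occupancy).

Downstream modules reproduce the standard analyses around these tracks:
read-level filters (insert size 50–500 bp inclusive; anomalous pileup
positions at Z > 7), quantile-group scaling (medians of the 1st and 20th
vigintiles mapped to 0/1), gene classification from an expression table,
strand-aware metagene profiles with SEM, Mann–Whitney and one-sided
signed-rank comparisons (exact distributions computed in-package),
window-Z enhancer calling from H3K27ac ChIP/input with time-course
classification (twofold up-regulation / constitutive fourfold
enrichment), stable nucleosome position calling, and a positional
stability test (replicate-vs-replicate against time-point-vs-time-point
nearest-peak distances, two-sample KS).

A first-class synthetic data module (`synthetic_genome_spec()`,
`build_genome()`, `simulate_*()`) generates a genome with planted
nucleosome occupancy/accessibility, concentration-dependent release,
GC bias, enhancer time courses and gene classes, so every estimator can
be checked against known truth.

## Worked example

```r
library(maccr)

spec <- synthetic_genome_spec(chrom_lengths = c(chr2L = 5e5L),
                              n_genes = 30, n_enhancers = 10, seed = 42)
genome <- build_genome(spec)
genome
#> synthetic_genome: 1 chrom (0.50 Mb), 2777 nucleosomes, 30 genes, 10 enhancers

# one titration series: 4 digestion depths, filtered (insert 50-500, Z > 7)
fragments <- lapply(1:4, function(lv)
  filter_fragments(simulate_titration_fragments(genome, "0h", lv, 2e5,
                                                seed = 100 + lv)))
fragments[[1]]
#> fragment_set: 195811 fragments (assay=mnase_h3, time_point=0h, level=1,
#>   replicate=1, gc_bias_strength=0, n_removed_insert=3934, n_removed_anomalous=255)

macc <- compute_macc(fragments, genome$gc_bins)   # bin, regress, GC-correct
series <- titration_series_from_fragments(fragments, 200, spec$chrom_lengths)
occupancy <- compute_occupancy(series, "raw")     # titration-averaged

truth <- genome$truth[["0h"]]
cor(track_values(truth$accessibility), track_values(macc$macc),
    method = "spearman", use = "complete.obs")
#> Spearman rho (true accessibility vs MACC): 0.957
cor(track_values(truth$occupancy), track_values(occupancy),
    method = "spearman")
#> Spearman rho (true occupancy vs occupancy): 0.920
```

The estimators recover the planted ground truth: MACC ranks bins by their
true accessibility (rho 0.96) and the titration average ranks them by true
occupancy (rho 0.92). The planted promoter nucleosome-depleted regions are
likewise visible in a TSS metagene profile (occupancy 77 CPM at the TSS
versus 409 CPM in the ±1 kb flanks in this simulation).

## Pipeline runner

A JSON run config wires the many files of a real experiment (assay × time
× level × replicate) to subcommands; `inst/cli/maccr-cli` exposes the same
through `Rscript`:

```sh
Rscript inst/cli/maccr-cli simulate --config run.json
Rscript inst/cli/maccr-cli macc     --config run.json
```

Subcommands: `simulate`, `filter`, `macc`, `occupancy`, `enhancers`,
`peaks`, `profile`, `compare`, `fraction`. Each writes its outputs
(bedGraph/BED/TSV) plus a manifest (parameters, package version, input
hashes) into the configured output directory; see `?read_run_config`.

## Vignette

`vignettes/macc-methods.Rmd` documents the model and estimators, the
design decisions taken where the method description leaves freedom, what
the synthetic generator does and does not emulate, and known limitations.
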