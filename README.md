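# fragsig

Multi-omic fragility signatures from replication timing, nascent
transcription and chromatin architecture.

## The science

Common fragile sites — the loci that break first when DNA replication
is stressed — are not defined by any single genomic feature. `fragsig`
implements a multilayer signature that identifies candidate fragile
genes as the conjunction of four conditions measured on independent
data types:

1. **Large gene body** (> 300 kb), from the gene annotation.
2. **High nascent transcription** (upper half of the expression
   distribution, quartiles q3/q4), from Bru-seq-style gene-body read
   counts normalized to per-kb reads-per-million.
3. **Replication-timing (RT) delay under mild replication stress**
   (aphidicolin, "APH"), from early/late S-phase Repli-seq counts:
   RT = log2(early/late) per 5-kb bin, quantile-normalized across
   samples, averaged into 100-kb windows, and flagged when the
   APH−control change exceeds a threshold calibrated as twice the
   standard deviation of technical-replicate differences (~1 RT unit)
   with a consistent sign across every replicate pair. Contiguous
   same-direction windows merge into differentially replicated regions,
   and k-means over the window-by-sample RT matrix names the RT
   signatures (e.g. "early_delayed": early-replicating in control,
   delayed under APH).
4. **Spanning a TAD boundary**, from Hi-C contact matrices via a
   diamond insulation (TAD-separation) score: boundaries are prominent
   local minima of the score, and a gene "spans" a boundary when the
   boundary midpoint falls strictly inside the gene body.

Within each candidate, the per-bin RT change traces a characteristic
**V shape** — maximal delay at a single vertex, tapering toward the
gene ends. `fragsig` localizes the vertex with a two-segment
piecewise-linear (hinge) least-squares fit and reports the surrounding
**core fragility region (CFR)**: the contiguous bins at least 80% as
delayed as the vertex.

Because the real datasets behind this kind of analysis are
multi-gigabyte sequencing deposits, the package ships a fully
specified synthetic-data generator (`simulate_dataset()`) with planted
ground truth — fragile genes that satisfy all four layers by
construction, plus intra-TAD delayed controls that exercise the
negative arm — so every stage is testable end to end on a laptop.

## Worked example

Simulate the default dataset (4 chromosomes x 50 Mb, 500 genes, 12
planted fragile genes + 12 intra-TAD delayed controls, V depth −1.5 RT
units, 4 + 4 replicates) and run the full pipeline:

```r
library(fragsig)

cfg <- simulation_config(seed = 1)
manifest <- simulate_dataset(cfg, "simdata")

pcfg <- pipeline_config(
  chrom_sizes   = manifest$chrom_sizes,
  samples       = manifest$samples,
  genes         = manifest$genes,
  nascent       = manifest$nascent,
  library_sizes = manifest$library_sizes,
  boundaries    = manifest$boundaries,
  out_dir       = "report")
res <- run_pipeline(pcfg)

fragility_funnel(res$calls)
#> # A tibble: 4 x 2
#>   cohort                       n
#>   <chr>                    <int>
#> 1 large                       56
#> 2 large_transcribed           40
#> 3 large_transcribed_delayed   24
#> 4 fragile_candidate           12
```

With this seed the run flags 59 RT-variable 100-kb windows, merging
into 34 differentially replicated regions (24 delayed, 10 advanced).
The screening funnel narrows 56 large genes to exactly the 12 planted
fragile genes — all 12 planted genes are recovered and none of the 12
intra-TAD delayed controls leak through (the boundary layer, not the
delay layer, separates them; the controls are all still detected as
RT-delayed). The five RT signature clusters include the canonical
`early_delayed` class (centroid control RT 1.64 → APH 0.43).

Each candidate carries a fitted V-shape; recovered vertex depths for
seed 1 range from −1.35 to −1.65 RT units around the planted −1.5,
e.g.:

```r
dplyr::select(dplyr::filter(res$cfr, gene_id == "gene_0002"),
              gene_id, vertex, depth, is_v, cfr_start, cfr_end)
#> # A tibble: 1 x 6
#>   gene_id    vertex depth is_v  cfr_start cfr_end
#>   <chr>       <dbl> <dbl> <lgl>     <dbl>   <dbl>
#> 1 gene_0002 7962500 -1.55 TRUE    7930000 8005000
```

(gene_0002: 468,919 bp, expression quartile q4, boundary-spanning,
delay magnitude −1.2 on the region layer.)

The report bundle in `report/` contains `candidates.bed`,
`gene_evidence.tsv` (every gene with all four component calls and the
V fit), `regions.tsv`, `signatures.tsv`, `funnel.tsv`, and
`run_log.tsv` with every effective parameter; rerunning with the same
configuration reproduces the files byte for byte.

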