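---
title: "Methods: the multilayer fragility signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multilayer fragility signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `fragsig`, every
default parameter with its rationale, the scope of the synthetic-data
generator, and the numerical choices made in the estimators. It is a
methods reference; the README holds a worked example with printed
output.

## 1. Data model

All coordinates are 0-based half-open (BED convention); 1-based inputs
(GTF) are converted at the parsing boundary. Tracks live on a fixed
bin frame from `tile_genome()`; masked bins are `NA`, never zero.
Multi-sample RT data is one long tibble keyed by
`(chrom, start, end, sample, condition, replicate)`.

## 2. Replication timing

Per 5-kb bin,

$$\mathrm{RT} = \log_2\frac{\text{early} + c}{\text{late} + c}$$

with pseudocount $c = 1$; positive RT means earlier replication. Bins
with fewer than `min_coverage = 10` combined reads are masked: a
log-ratio over a handful of reads is sampling noise. Profiles are
quantile-normalized across all samples (`limma::normalizeQuantiles`)
on jointly unmasked bins, so samples share one genome-wide RT
distribution while each sample's ranking is untouched. Smoothing
(`gauss_smooth()`) convolves each contiguous unmasked run with a
Gaussian kernel truncated at $4\sigma$ and renormalized at run edges,
so kernel mass falling outside a run is redistributed instead of
counted as zero signal.

## 3. RT variability

RT is averaged into 100-kb windows (jointly unmasked bins only;
windows more than half masked are dropped). A window is **RT-variable**
when

* $|\overline{\mathrm{RT}}_{\mathrm{APH}} -
  \overline{\mathrm{RT}}_{\mathrm{ctrl}}| \ge \tau$, and
* every cross-condition replicate pair agrees on the sign of the
  change (equivalently, the two conditions' replicate value ranges do
  not interleave), suppressing single-replicate artifacts.

The threshold $\tau$ defaults to 1.0 RT units and can be calibrated as
**twice the standard deviation of within-condition replicate pairwise
differences** (`estimate_variability_threshold()`); replicate noise of
~0.35 RT units gives pairwise-difference SD ~0.5 and hence $\tau
\approx 1$. Contiguous same-direction variable windows merge into
differentially replicated regions (`merge_contiguous()`); delayed and
advanced runs never join.

RT signatures are k-means clusters (k = 5, 50 restarts,
`stats::kmeans`) of the flagged-window-by-sample RT matrix; each
cluster is labeled from its centroid condition means trisected at RT
−0.5/0.5 (e.g. control early, APH mid → `early_delayed`) and tested
with a paired t-test (control vs APH window means) with
Benjamini–Hochberg adjustment.

## 4. Nascent transcription

Gene-body read density is intron-inclusive (appropriate for nascent
RNA): reads overlapping the gene body — partial bins prorated by
overlapped fraction — scaled by $10^6/\text{library size}$ and divided
by gene length in kb (per-kb RPM). Genes below `silence_floor = 0.5`
are silent. Expression quartiles are rank-based (`dplyr::ntile`); q1
contains the silent genes, and **highly transcribed** means q3 or q4.
Sizes: large > 300 kb (the classic large-gene fragility cutoff),
medium 250–300 kb, small below; large genes split into length
quartile subgroups L1 (largest) to L4.

## 5. TAD boundaries

For a symmetric contact matrix, the diamond insulation score at bin
$i$ with half-width $w$ (default 10 bins) is

$$s_i = \log_2 \frac{\mathrm{mean}\,M[i-w..i-1,\; i+1..i+w]}
                    {\langle \text{diamond} \rangle_\text{chrom}}$$

computed with a summed-area table (exact, $O(n^2)$ preprocessing,
$O(1)$ per diamond) and invariant to global matrix scaling. Bins
within $w$ of a chromosome end are masked. An optional multi-window
variant averages the single-window scores (e.g. `windows = c(5, 10,
15)`), damping spurious shallow minima. `call_boundaries()` keeps
local minima with walk-based prominence ≥ `min_depth = 0.3`, accepted
greedily from the deepest up with ≥ 4 bins separation. A gene is
boundary-spanning iff some boundary **midpoint lies strictly inside**
the gene body — a midpoint exactly at a gene edge does not count.

CTCF enrichment at boundaries uses an in-process shuffle test:
size-matched intervals placed uniformly per chromosome, mutually
disjoint, excluding the observed boundary loci (the equivalent of
`bedtools shuffle -noOverlapping -excl`), with the add-one empirical
p-value $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{iter})$,
which is never 0 and is uniform on a grid under the null.

## 6. The fragility call and the V shape

A gene is a **fragile candidate** iff it is large ∧ highly transcribed
∧ RT-delayed (overlaps a delayed region) ∧ boundary-spanning. The
four components are reported independently; the intermediate cohort
sizes form the screening funnel.

The candidate's core fragility region comes from the per-bin RT change
$\Delta_i$ (APH − control condition means) over the gene ± 500 kb,
referenced to the flank median. The vertex is located by a
**two-segment piecewise-linear (hinge) least-squares fit**: for every
candidate vertex $v$ in the gene body, fit

$$\Delta(x) \approx a + b_L\,(v - x)_+ + b_R\,(x - v)_+$$

and keep the $v$ minimizing the residual sum of squares; the depth is
the fitted intercept $a$. This uses every body bin and is therefore
robust both to per-bin noise at the flat V bottom and to the asymmetry
bias of a smoothed argmin (which drifts toward the shallow arm; it
remains available as `method = "argmin"`). A V is called when depth ≤
−0.5 RT units and the smoothed profile rises at least 0.25 on both
sides; the CFR is the contiguous run of bins at least 80%
(`cfr_fraction`) as delayed as the vertex.

## 7. The synthetic-data generator

`simulate_dataset()` is a deterministic function of
`simulation_config(seed, ...)`; identical calls give byte-identical
files. Defaults and rationale:

| Parameter | Default | Rationale |
|---|---|---|
| genome | 4 × 50 Mb | ~100 TADs and 500 genes at minute-scale runtimes |
| gene lengths | log-normal, meanlog log(4e4), sdlog 0.9; 8% Pareto tail (α = 2.5) above 300 kb | body of typical genes plus a heavy large-gene tail |
| zero inflation | 0.2 | silent genes must fit inside quartile q1 |
| expression | log-normal meanlog log(2), sdlog 1.2 | wide positive scale for quartile structure |
| TAD spacing | U(0.4, 1.2 Mb) | typical TAD sizes |
| planted fragile / controls | 12 / 12, 350–600 kb, expression at the 0.9 quantile ×U(1,2) | all four layers satisfied by construction; controls exercise the negative arm |
| V depth | −1.5 RT units, linear to 0 at gene edges | well above the 1.0 threshold, below the RT range |
| advanced bumps | 10 × 300 kb, +1.2, clear of genes | non-delay variability for the region/band layers |
| replicates | 4 + 4, latent RT noise SD 0.2 | realistic replicate concordance |
| reads | 200 per 5-kb bin, binomial early/late | Poisson-scale count noise |
| link | $p_\text{early} = 1/(1 + 2^{-\mathrm{RT}})$ | base-2 logistic, so the latent RT field and measured log2(early/late) share a scale and RT = 0 gives p = 0.5 |

The latent control RT per chromosome is a Gaussian-smoothed random
field (SD 60 bins) rescaled to [−3, 3]. Nascent counts are Poisson
with rate = background (0.05/kb bin) + expression level inside gene
bodies; contact matrices decay as $(1+|i-j|)^{-1}$, divided by
`contrast = 10` across planted boundaries, Poisson-sampled and
symmetric by construction.

**Scope and limitations.** The generator reproduces the *structure*
the pipeline targets — planted conjunctions, V-shaped deltas, TAD
blocks — not sequence realism: no mappability or GC bias, no
fork-level replication dynamics, no transcription change under stress
(both conditions share expression), and gene placement is uniform
rather than clustered. Quantile normalization partially absorbs
planted condition differences by construction; parameter-recovery
checks of the planted depth are therefore defined on raw
(pre-normalization) profiles, while the end-to-end pipeline uses the
normalized path.

## 8. Numerical choices

* Rank-based quantiles (`ntile`) everywhere thirds/fourths are needed:
  deterministic, and exact to within one element.
* The separation score's summed-area table is exact (no FFT or
  approximation); sums are over raw counts, so the score is scale-free
  by construction.
* The shuffle test resamples only the offending intervals each round
  (vectorized rejection), keeping thousands of iterations in-process.
* `set.seed` is taken exactly once per exported stochastic entry point
  (simulation stages use `seed`, `seed+1`, `seed+2`, `seed+3` so each
  data layer is independently reproducible).
* Reports contain no timestamps; reruns with an identical
  configuration are byte-identical.

## 9. Running the pipeline

```{r}
library(fragsig)
manifest <- simulate_dataset(simulation_config(seed = 1), "simdata")
pcfg <- pipeline_config(
  chrom_sizes = manifest$chrom_sizes, samples = manifest$samples,
  genes = manifest$genes, nascent = manifest$nascent,
  library_sizes = manifest$library_sizes,
  boundaries = manifest$boundaries, out_dir = "report")
res <- run_pipeline(pcfg)
fragility_funnel(res$calls)
```

See the README for the printed results of this exact run.
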