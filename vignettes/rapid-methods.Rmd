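---
title: "Polymerase DamID footprinting: models, parameters and design choices"
author: "rapidfoot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polymerase DamID footprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapidfoot)
```

## The assay and its signal model

RNA Polymerase DamID fuses the *E. coli* Dam methyltransferase to a subunit
shared by all three RNA polymerases, so that transcription leaves adenine
methylation marks on GATC motifs across transcribed gene bodies. Methylated
GATC sites are cleaved by DpnI and the intervening restriction fragments are
adapter-amplified and sequenced as long-read amplicons. A second animal
expressing a freely diffusing Dam fusion (Dam-only control) methylates GATC
sites in proportion to chromatin accessibility; the log2 ratio of
fusion-library coverage over control coverage per restriction fragment is the
polymerase occupancy track.

Two properties of this chemistry shape everything downstream:

* **The unit of resolution is the GATC fragment**, the interval between
  consecutive GATC motifs — in *C. elegans* one motif per ~374 bp on average
  (median spacing ~210 bp). Signal cannot be localized more finely.
* **The signal saturates.** Once a fragment is fully methylated, further
  transcription adds nothing: the dynamic range is compressed at the top
  (a plateau), and lowly expressed genes are rarely methylated at all. The
  occupancy value is a cumulative, stochastic average over cells and over
  the time since the last DNA replication erased the marks.

## Pipeline stages

### 1. GATC indexing

`gatc_index()` scans each chromosome for the palindromic 4-mer. Matching is
case-insensitive (soft-masked genomes keep their motifs) and windows
containing `N` never match. All internal coordinates are 0-based half-open;
BED output stays 0-based, GFF input is converted from 1-based closed. One
convention everywhere avoids off-by-one drift between stages.

Fragment boundaries are placed at motif *start* positions rather than at the
biological DpnI cut site two bases in. The end-matching tolerance of the
amplicon filter (8 bp) dwarfs that 2 bp offset, so a single documented
convention wins over biochemical exactness.

Spacing statistics are defined as differences of consecutive motif starts
within a chromosome, pooled genome-wide for the mean and median. An
alternative reading of "one site every X bp" is genome length divided by
motif count; the two differ only through chromosome-end effects, and the
pooled-difference definition is the one reported.

### 2. Amplicon end validation

A genuine DamID amplicon begins and ends at methylated GATC sites, so
`filter_alignments()` keeps a read only when **both** aligned ends lie within
`end_tolerance` (default 8 bp, inclusive) of a GATC motif. Distance is
measured to the 4-bp motif interval — zero anywhere inside it — because the
assay does not pin the end to a specific anchor base; any anchor convention
differs by at most 3 bp, absorbed by the tolerance. The read "end" is the
aligned reference span with soft clips excluded: adapter and barcode
remnants appear as clips, and the genomic footprint is what matters.
Secondary and supplementary alignments are dropped by default and the
mapping-quality floor is 10: amplicons are short unique fragments and
multimappers would inflate fragment counts. Both are tunable.

`count_fragments()` increments a fragment when its entire interval lies
inside the read span widened by the tolerance. A true amplicon is a union of
consecutive complete fragments; midpoint or fractional-overlap rules would
either drop edge fragments under jitter or count partial overlaps that the
chemistry forbids. Reads that cover no complete fragment are tallied as
anomalous rather than silently dropped.

### 3. Occupancy normalization

`normalize_counts()` computes, per fragment,

$$\mathrm{score}_i \;=\; \log_2\frac{f_i/F + \psi'}{c_i/C + \psi'}$$

with $F, C$ the library totals and $\psi'$ a pseudocount of 0.5 on the
counts-per-million scale. Total-count scaling is the default; an optional
`kde_mode` rescaling subtracts the kernel-density mode of the score
distribution, appropriate when most fragments are unbound so the modal
fragment is background. No smoothing is applied: the Dam-only profile
already serves as both the depth and the accessibility control.

The ChIP-comparison path (`chip_log2_ratio()`) is separate and uses the
convention of additive pseudocount 8 on depth-equalized bin counts. One
subtlety is documented rather than hidden: with an additive pseudocount,
depth invariance holds only when the reference depth the libraries are
scaled to is held fixed. The `ref_depth` argument defaults to the mean of
the two observed totals; pass a constant when comparing across many library
pairs.

### 4. Gene calls

`gene_occupancy()` aggregates the track over the annotated gene body —
start to end, introns included, since the polymerase transits introns and
the DNA-level signal cannot resolve isoforms — as the overlap-length
weighted mean of fragment scores (exactly equal to the per-base mean).

`call_expressed()` tests each gene against a **stratified permutation
null**: for a gene covering $k$ fragments, the null statistic is the mean of
$k$ fragment scores drawn from the genome-wide score pool, recomputed per
$k$-stratum from `n_permutations` draws (default 10,000). P-values are
plus-one-corrected empirical tail fractions, and Benjamini–Hochberg
adjustment yields the FDR. This choice is distribution-free, respects the
strong dependence of a gene's score variance on its fragment count, and is
exactly reproducible under a seed. The implementation draws one
max-$k$ sample per permutation and reads every stratum's mean off its
cumulative sum, so the 50-run calibration experiment in the test suite runs
in seconds.

Set algebra then follows the standard tissue-profiling definitions:
**detected** = FDR < 0.05 in at least one replicate, **consistently
detected** = in all replicates, **unique** = in exactly one tissue's
consistent set (`tissue_partition()`), with all Venn region counts reported.
No occupancy-effect-size threshold is layered on top of the set difference,
because none is part of the definitions.

`marker_candidates()` refines a unique set by removing genes detected in any
whole-animal replicate — the most stringent reading of "detected in at least
one worm-wide sample" — and genes with another transcript ending strictly
less than 200 bp upstream (possible operons, where a promoter fusion would
not report the candidate's own transcription). Upstream is strand-aware, and
by default only same-strand neighbors count, since operons run in one
direction; `neighbor_strand = "any"` exposes the stricter variant.

### 5. Profiles and validation statistics

`metagene()` rescales each gene body to `n_body_bins` bins of per-base mean
score (bases inherit their fragment's score), adds fixed-resolution flanks,
reverses minus-strand genes so the TSS is always left, and averages across
genes without weighting. Genes shorter than one base per bin are skipped and
counted.

`ranked_bin_comparison()` sorts genes by occupancy (ascending, ties broken
by gene id for determinism) and reports mean expression per block of 690
genes — the binning used for semi-quantitative comparison against RNA-seq.

`bootstrap_tpr()` turns $x$ positive outcomes among $n$ validation readouts
into a percentile bootstrap CI: resampling $n$ binary outcomes with
replacement is exactly a Binomial($n$, $x/n$) draw, which is how the
resamples are generated; B = 10,000 by default and the percentile interval
converges to the exact binomial quantiles. For 8 positives of 11 readouts
the 2.5th percentile is 5/11 ≈ 45%; note that a plain percentile interval
puts the upper bound at 11/11 = 100% — reported upper bounds near 88% for
this ratio require a different resampling scheme, so only the lower bound
should be treated as scheme-independent. `extrapolate_expressed()` scales
the interval to a detected-gene count, optionally rounding to the nearest
hundred for headline-style figures.

## The synthetic-data generator

`simulate_rapid()` emulates the statistical structure the pipeline assumes,
so that every stage is testable with known truth and no sequencing data:

* **Genome**: i.i.d. uniform bases (background GATC rate 1/256 per
  position), with optional extra motifs planted at a Poisson rate.
* **Annotation**: non-overlapping genes with log-normal lengths around
  2 kb, random strands, uniform intergenic gaps (500–2000 bp by default;
  forceable for operon-rule tests). Exactly
  `round(expressed_fraction * n_genes)` genes receive log-normal expression
  levels; the rest are silent.
* **Methylation**: a fragment overlapping a gene expressed at level $e$ is
  methylated with probability $1 - e^{-\kappa e}$ — the simplest saturating
  kinetics producing the plateau the assay exhibits. $\kappa = 1$ with
  expression meanlog 0.5 and sdlog 1 puts typical expressed genes at
  0.4–0.99 methylation, spanning the near-linear and saturated regimes.
* **Accessibility**: per-fragment log-normal weights (sdlog 0.3) multiply
  *both* the fusion and control sampling weights — exactly the nuisance the
  Dam-only ratio is designed to cancel.
* **Libraries**: amplicons are runs of 1–3 consecutive fragments with
  geometric length decay (mimicking size selection), sampled proportional to
  `accessibility * (methylation + baseline)` for the fusion role
  (baseline 0.05 for background amplification) or accessibility alone for
  the control. Ends sit at the bounding motifs with uniform ±8 bp jitter;
  10% of reads get one end displaced at least 9 bp from any motif, which the
  amplicon filter must reject. Records are emitted as coordinate-level
  alignments (and optionally SAM), so no aligner is involved.

The default parameters — one 2 Mb chromosome, 500 genes, 30% expressed,
200,000 reads per library — constitute the small study condition used by
the end-to-end tests: large enough for stable FDR calibration and decile
dose-response curves, small enough that the full suite runs in under a
minute. What the simulator deliberately does **not** model: PCR-cycle and
nanopore error processes, replication-timing erasure of methylation,
GC- or mappability-bias, isoform structure, and real operon annotation.
Passing tests therefore demonstrate correctness of the computational method
under its own assumptions, not performance on real libraries.

## Numerical choices and degenerate inputs

* Empirical p-values are plus-one corrected, so no p is ever 0 and the BH
  step-up is well defined at any B.
* Null lookups use sorted arrays with exact tie handling
  (`findInterval(..., left.open = TRUE)`), so a gene exactly at a null
  quantile is counted conservatively.
* A zero-total library, mismatched fragment lists, genes outside chromosome
  bounds, empty gene universes and zero-variance correlation inputs are all
  hard errors or warned `NA`s, never silent zeros.
* Fragment-count strata with more fragments than the genome holds fall back
  to sampling with replacement, with a warning.
* Every random stage takes an explicit seed; the pipeline derives per-stage
  seeds from the global seed by fixed offsets, so adding a stage never
  shifts another stage's stream, and rerunning a config reproduces
  byte-identical outputs (checksummed in the manifest).

## Known limitations

GATC-poor genes yield weak signal regardless of transcription: fragment
resolution is a floor, not a parameter. The plateau compresses
quantification at the top of the expression range, so occupancy is best read
as a detector with a monotone but saturating dose-response rather than an
expression estimate. The permutation null treats fragments as exchangeable
genome-wide; strong large-scale accessibility artifacts that survive the
Dam-only ratio would violate that assumption and inflate calls. Replicate
handling happens at the gene-call stage (set algebra), not by track merging.
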