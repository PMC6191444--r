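---
title: "chromdiff: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromdiff: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models, their assumptions, the tunable parameters with
their defaults and units, what the synthetic-data generator does and does
not emulate, and the choices made where the underlying procedures were
genuinely open.

## Coordinates and interval algebra

All coordinates are 0-based half-open at file boundaries (BED native) and
1-based closed inside `GRanges`; the conversion happens only in
`read_bed()` / `write_bed()`. Overlap arithmetic is strand-blind (peak and
state comparisons in this field ignore strand); strand is carried and
consumed only by the meta-gene module. Half-open semantics imply that
book-ended intervals (`[0,100)`, `[100,200)`) do **not** merge at
`gap = 0`; `merge_overlapping(s, gap = g)` merges intervals separated by
fewer than `g` bp. No blacklist-region exclusion is applied anywhere; the
reader validates against the declared assembly instead.

## Coverage model

`extend_and_pileup()` extends each read from its 5′ end to the expected
fragment length (default **150 bp**, the nucleosomal fragment size after
MNase digestion) and adds 1 over the extended fragment, clipped at
chromosome ends; clipped bases are counted, not fatal. `normalize_1x()`
rescales so the genome-wide mean per-base value is exactly 1, which makes
tracks of different library sizes comparable.

Region counting uses the **fragment-midpoint rule**: a read is counted in
a region iff the midpoint of its (clipped) extended fragment lies in the
region. The rule is a deliberate choice — "count of reads overlapping a
region" admits several readings, and midpoint counting guarantees that no
read is counted twice across adjacent regions, which the size-factor
estimator and the exact test both assume. Any-overlap counting would
inflate counts at region boundaries by up to one fragment length.

`median_of_ratios_size_factors()` is the classical estimator: restrict to
regions with positive counts in every sample, divide each count by the
across-sample geometric mean of its region, and take the per-sample
median. We use the arithmetic median of ratios; the reference
implementation in the DESeq2 package takes the median on the log scale,
which differs only through even-*n* median interpolation (relative
differences ~1e-5 on typical matrices; the test suite cross-checks
against it at 1e-3).

## Meta-gene matrices

`build_metagene()` uses **6000 bp** flanks in **50 bp** bins (120 bins per
flank) and **120** variable-width gene-body bins. Body bins are
*fractional slices*: bin $k$ of a gene of length $L$ covers
$[kL/120, (k+1)L/120)$ in real-valued base coordinates, and its mean is
the exact length-weighted average of the per-base signal (computed from
the cumulative sum with fractional end corrections). This makes the mean
over body bins equal the gene-body mean to floating-point accuracy for
genes of any length ≥ 120 bp — the conservation invariant the tests
enforce — whereas floor-division binning would not. Minus-strand rows are
reversed into 5′→3′ orientation. Genes shorter than 120 bp or whose
flanks leave the chromosome are excluded and recorded.

The clustering method behind the gene-body heatmap was not prescribed, so
the package declares a substitute: k-means on row-standardized profiles
(`k = 3` by default, matching the visible cluster count in such heatmaps;
10 restarts; fixed seed). Labels are renumbered by decreasing mean body
signal, so "cluster 1" is always the body-signal-richest group, the
analogue of the H3K36me3-enriched gene-body cluster. `k` equal to the
number of genes degenerates to one gene per cluster, handled without
invoking k-means.

`compare_body_vs_downstream()` compares, per gene, the mean signal over a
3′-body window (default: the final 25% of the body; configurable in bp)
with an equal-width window immediately downstream of the TES,
strand-aware. Both the paired signed-rank p-value (the design is paired
per gene) and the unpaired rank-sum p-value are reported, since the
latter is the test named in the field's reports. Exact small-sample null
distributions are used below n = 50 without ties (via `wilcox.test`), and
the suite verifies the exact path against sign-assignment enumeration at
n = 8.

## Chromatin-state enrichment

For peak set $P$ and state $s$ with territory $W_s$:
$O_s = \mathrm{overlap}(P, W_s)/|P|$, $E_s = |W_s|/G$ with $G$ the total
genome size, reported with $\log_2(O_s/E_s)$. Peaks are unioned before
overlap (otherwise $O$ is not a proper fraction and $\sum_s O_s$ can
exceed 1); `union = FALSE` is available for sensitivity analysis. States
with zero observed overlap report $-\infty$ with an explicit flag rather
than a clipped value; the plotting helper clips at a configurable floor.
On tiling segmentations $\sum_s O_s = 1$ exactly, which the tests use as
a conservation check. Note that with many peaks the union step merges
colliding peaks preferentially in the enriched state, biasing the
measured log2 ratio slightly below the placement-scheme expectation; at
1,000 peaks on the default genome the bias is within the ±0.2 log2 units
the acceptance property allows.

## Co-occupancy

A peak of factor A is *shared* if it overlaps any B peak (≥ 1 bp).
A non-overlapping A peak is *unique_A* only if A's normalized count over
the peak interval is at least `fold_threshold` (default **2**) times B's;
otherwise B shows sub-peak-call-level binding there and the peak is
demoted to shared. Normalization uses median-of-ratios factors estimated
over the merged union of both peak sets; a pseudocount (default 1) bounds
the ratio when counts are small. The rule is monotone: raising the
threshold can only move peaks from unique to shared, so the pure
interval-overlap Venn is the `fold_threshold → 0` limit and "everything
shared" the `→ ∞` limit. The pseudocount makes classification only
asymptotically invariant to uniform rescaling of one factor's library;
at realistic counts (tens per peak) calls are stable, which the suite
checks by tripling one library.

## Consensus differential binding

**Window route.** The genome is tiled with 100-bp bins every 300 bp —
a sparse tiling with 200-bp gaps, exactly as specified; a dense grid is a
parameter change away. Scaling factors come from 10-kb bins via a
trimmed mean of per-bin log2 ratios against the sample with library size
closest to the mean (30% trim on M each tail, 5% on A each tail),
centered to geometric mean 1; computed on raw bin counts, the factors
absorb library-size differences ("basically normalizing for total read
count"). Bins below a mean normalized count of 5 are not tested.

The per-bin test is a two-sided **conditional NB exact test**: with a
common per-replicate mean under the null and a common dispersion
$\alpha$, the control total $Y_1$ given the bin total $t$ follows a
negative hypergeometric law that does not depend on the mean — only on
$\alpha$ and the replicate counts — so the test needs no mean estimate.
$\alpha$ is estimated by method of moments on normalized counts, pooled
within 10 abundance strata ($\hat\alpha = \max(0, \sum_i (s_i^2 - \bar
z_i) / \sum_i \bar z_i^2)$ over within-condition moments); with a single
replicate per condition it falls back to Poisson ($\alpha = 0$, the
binomial conditional test) with a warning. Significant bins use **raw
p < 0.001** with no multiplicity adjustment — that is the prescribed
selection rule for this route; the calibration test verifies the null
p < 0.001 fraction stays in [0.0005, 0.002] at 10,000 bins. Significant
bins whose starts lie within **2 kb** (start-to-start, configurable) are
chained into regions.

The published analysis ran this scaffolding through csaw's
quasi-likelihood machinery; the test internals were not specified, so the
exact conditional test above is a declared substitute. The acceptance
surface is planted-truth recovery, not equality with csaw.

**Peak route.** Peaks present in both replicates of a condition (≥ 1 bp
overlap) are kept, combined across conditions, and overlapping peaks
merged into single features spanning the originals. Features are counted
per sample, normalized by median-of-ratios, and tested with an NB Wald
test (GLM with log link, method-of-moments dispersion as above, BH
adjustment at 0.05). This substitutes for a DESeq2 run in the same
declared sense; dispersion shrinkage and LFC shrinkage are deliberately
omitted — at desk scale the MoM estimate pooled over strata is stable,
and unshrunken LFCs keep the planted-effect recovery interpretable.

**Consensus.** Window regions are retained iff they overlap a
significant peak feature; by default the two routes must agree on the
direction of change (an unspecified detail — requiring agreement prevents
a region from being reported with contradictory signs; a flag disables
it). `direction_summary()` reports induced/repressed fractions.

## Histone-PTM quantification

Within an isobaric group, member weights are the **arithmetic mean** of
the three unique MS2 fragment integrals ("averaged integrals" read as the
plain mean; a geometric-mean option is exposed). The shared MS1 area is
split proportionally to weights, with the largest member pinned so the
split sums to the shared area exactly. Missing fragments average over
the present ones; an all-zero group splits equally with a warning.
Percentages are effective areas over the per-peptide, per-sample total;
input normalization is a **ratio** of percentages (reading "normalized to
percentage values of Input" in its most direct sense; a difference mode
is available by flag).

## qPCR

Percent input adjusts the input Ct by $\log_2(1/f)$ for input fraction
$f$ (a required parameter — the fraction used in any given experiment is
not inferable from Ct values), then reports $100 \cdot 2^{Ct'_{in} -
Ct_{IP}}$ per replicate with mean and SEM. Relative expression is
$2^{-\Delta\Delta Ct}$ with SEM computed over replicate-level
$\Delta\Delta Ct$ and the error-bar range $[2^{-\Delta\Delta Ct - SEM},
2^{-\Delta\Delta Ct + SEM}]$ — since the fold is $2^{-\Delta\Delta Ct}$,
the $+SEM$ branch is the upper bound. No amplification-efficiency
correction is applied.

## The synthetic-data generator

`simulation_config()` defines the study conditions; its defaults are
fixed once and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| genome | 3 × 2 Mb | desk-scale stand-in for a mammalian genome |
| states | 10, on 1-kb tiles, stay-probability 0.85 | 10-state annotation granularity; ~6.7-kb mean segments |
| peak placement | weight 5 on state 3 | planted positive control for state enrichment |
| genes | 300, lognormal lengths ≥ 2 kb | enough rows for clustering; flanks stay on-chromosome |
| peaks per factor | 300, widths ~lognormal, median 500 bp | typical point-source peak scale |
| reads per sample | 100,000 | ~2.5× background coverage, deep for 6 Mb |
| FRiP | 0.4 | strong native-ChIP enrichment |
| replicates | 2 per condition | the study design |
| effect fold | 3 | planted differential-acetylation effect |
| differential sites | 30 | minority of peaks, as observed |
| NB dispersion | 0.02 | highly reproducible native-ChIP replicates |
| library jitter | ±20% | exercises normalization honestly |

The dispersion default deserves its power argument: with 2 + 2
replicates and raw p < 0.001, the log count-ratio of condition totals at
a bin with mean $\mu$ has standard deviation roughly
$\sqrt{2}\sqrt{\alpha/2 + 1/(2\mu)}$. At $\alpha = 0.05$ the 3-fold
planted effect sits near the detection boundary *regardless of depth*
(the dispersion term dominates), while at $\alpha = 0.02$ it is
comfortably detectable at the default depth. The generator therefore
models tightly reproducible replicates — consistent with differential
sites being describable as "reproducibly detectable" — and the
planted-recovery property (≥ 90% consensus sensitivity, ≤ 10% FDR,
median estimated log2FC within ±0.5 of log2 3) is part of the study
conditions rather than a post-hoc calibration.

What the generator does **not** emulate: sequence content, mappability
and GC bias, PCR duplication, fraglen variability, spike-ins, graded
knockdown efficiency (the planted effect is binary per site), and
correlated peak shapes. Passing tests therefore demonstrate the
correctness and calibration of the computations under a clean generative
model, not robustness to those artefacts in real data.

Determinism: one master seed; every stage derives sub-seeds through a
fixed modular map (exact in doubles, below 2^31), so a pipeline run is
byte-reproducible file by file, which the suite asserts.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on generated data:
200 random 100-kb genomes for the interval-algebra oracles, 10,000 bins
for null calibration, 1,000 peaks for the state-enrichment planting, 500
genes for meta-gene conservation, 20 (suite) or 10 (script) seeded
consensus runs at the default conditions, and 200 draws for the noisy
isobaric recovery. These sizes were chosen as the smallest at which the
measured properties are stable.

## Known limitations

* The window-route p-values are exact only conditional on the estimated
  dispersion; with very few tested bins the stratum estimates are noisy.
* The Wald test loses accuracy for features with zero counts in one
  condition (no shrinkage); such features are reported with finite
  pseudocounted fold changes but their p-values come from the GLM fit.
* The co-occupancy normalization universe is the union of both peak
  sets; if the two factors' libraries differ grossly in signal-to-noise,
  factors estimated there may not transfer perfectly to individual peaks.
* Meta-gene flanks must lie on-chromosome; near-telomeric genes are
  dropped rather than zero-padded.
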