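---
title: "Measuring Pol II elongation, pausing and mRNA decay kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Pol II elongation, pausing and mRNA decay kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polkinetics)
```

# Scope

`polkinetics` quantifies RNA polymerase II transcription kinetics and mRNA
turnover from sequencing-derived signal tracks:

* **Elongation rate** from a DRB-washout PRO-seq time course, by calling the
  leading edge of the wave of nascent transcription that sweeps down each
  gene after the CDK9 inhibitor is removed.
* **Stalling index** (promoter-proximal accumulation) and **processivity
  index** from PRO-seq or Pol II ChIP-seq tracks.
* **mRNA half-life** from metabolic-labeling (SLAM-seq style) T-to-C
  conversion rates during a chase.
* **Transcript buffering** as the per-gene difference between steady-state
  (RNA-seq) and nascent (PRO-seq) log2 fold changes.

Every stage has a synthetic-data generator with known ground truth, so the
whole pipeline is testable by parameter recovery without any sequencing
data. Read alignment, differential-expression testing, and read-level
conversion calling are out of scope: the package starts from per-base
signal (bedGraph), interval annotations (BED6/GTF) and per-gene conversion
tables (TSV).

# Coordinate and track conventions

Internally, intervals are Bioconductor `GRanges` (1-based, closed); BED and
bedGraph files are converted at the I/O boundary. Signal lives in
`SignalTrack` objects: run-length-encoded per-base vectors, one per strand
(`+`/`-`) for PRO-seq 5'-end counts, or a single unstranded vector for ChIP
coverage. PRO-seq signal is the count of read 5' ends: one unit per read at
its strand-aware 5' coordinate, so track totals equal read counts, and
scaling by a normalization factor scales totals exactly.

The read's alignment strand is taken as the transcription strand;
`flip_strand = TRUE` in `five_prime_track()` covers library protocols where
the adaptor scheme inverts it (the 5' end is then recomputed on the flipped
strand).

# Region definitions

TSS regions (e.g. FANTOM CAGE clusters) are extended into **promoters** of
`2*flank + 1` bp (default 501 bp) around an anchor point. The anchor is the
strand-aware *downstream boundary* of the TSS region. The alternative
reading — anchoring at the region midpoint — is available via
`anchor = "midpoint"`, because the two natural phrasings ("the end of the
TSS region" vs "the TSS") conflict when TSS regions are wider than a
single base; the downstream boundary is the default as the more specific
phrasing.

**Gene bodies** run from the promoter end to the representative transcript
end: the modal strand-aware 3' end over annotated isoforms (exact
coordinate equality, no fuzz window), ties broken by the longest isoform.
Genes whose representative end falls upstream of the promoter end are
degenerate and excluded. Promoters are assigned to the nearest same-strand
transcript and dropped beyond 2 kb; when a transcript overlaps several TSS
regions, the representative promoter is the one with the highest mean
PRO-seq signal (leftmost on ties, for determinism).

# Spike-in normalization

PRO-seq samples are scaled by factors proportional to `1 / spike-in reads`
and rescaled to geometric mean 1 — so a sample in which proportionally more
exogenous material was recovered is scaled *down*, and the average library
is untouched. ChIP-seq tracks are divided by the human/mouse unique-read
ratio, which has the same orientation. This single fixed orientation is a
deliberate choice: stated as a multiplier, "target/spike" and
"1/spike" differ only by the geometric-mean rescaling when target depths
are equal, and internal consistency across assay types matters more than
either literal phrasing. RPKM values used by the expression filters are
computed against the *raw* target-genome library size, since those filters
compare regions within one sample.

# The leading-edge wave caller

After DRB washout, polymerases released from the promoter advance at a
gene-specific velocity, producing a front of nascent signal at distance
`v * t` from the TSS. The caller works on **censored difference tracks**
(`max(0, s_t - s_0)`): subtracting the residual t = 0 signal prevents
merging waves with standing signal of downstream genes in head-to-tail
orientation, and censoring keeps covered-base counting meaningful.

Each chromosome/strand is split into 1 kb tiles; per tile, covered bases
(signal > 0) are counted and signal is summed. Covered-base counts are
smoothed non-iteratively, `smoothed_n = max(raw_{n-1}, raw_n)` ("preceding"
= lower genomic coordinate on both strands; the method runs on genome
tracks before any gene assignment). Tiles with smoothed coverage below 25%
of the tile or summed signal below 0.1 are removed; survivors within 4 kb
are merged; regions shorter than 3 kb are dropped. All thresholds are
inclusive on the keep side (a region of exactly 3000 bp survives), because
the filter is phrased as removing regions *shorter than* 3 kb.

Regions are annotated to the closest upstream TSS. One numerical subtlety
is resolved here: regions are tile-quantized, so a gene's own TSS almost
always lies a few hundred bases *inside* its region's first tile. Upstream
eligibility is therefore judged against the region's strand-aware 3'
(leading-edge) boundary, making an in-region TSS eligible; judging against
the 5' boundary (available as `anchor = "start"`) would assign nearly every
wave to the previous gene on the chromosome.

The **leading edge** is the strand-aware 3'-most region boundary per gene —
tile resolution, deliberately without sub-tile refinement, matching the
tile-based construction. The elongation rate is TSS-to-edge distance over
the nominal washout time (no lag correction), in kb/min. Genes must have a
region at *every* condition and timepoint to enter the rate table; medians
are reported per condition over a caller-supplied subset (typically genes
longer than 100 kb, where the wave is long enough to resolve).

Expected accuracy: with 1 kb tiles the edge is quantized and the smoothing
rule extends it by about one tile, so single-gene rates at t = 10 min carry
a few percent of systematic error — the acceptance bar (median absolute
relative error < 15%) reflects this resolution, not fitting noise.

The **processivity index** is `log10(distal/proximal)` reads in the gene
body. The source method never defines the two windows; the package
defaults to the first and last 10% of the gene body (exposed as
`proximal_frac`/`distal_frac`), which keeps the index 0-centred on uniform
signal.

# Stalling index, filters, metagene profiles

The stalling index is simply promoter count / body count (`NA` on empty
bodies). Two gene filters precede comparative analyses: genes with
wild-type RPKM > 8 in the 250 bp window from 500 to 250 bp upstream of the
promoter 5' edge are removed as read-through candidates, and genes with
promoter RPKM < 2 in *all* samples are removed as non-expressed. The rules
are independent, hence order-independent; the audit log records which rule
fired.

Metagene profiles orient each region 5' to 3', average into 100 equal bins
(fractional base assignment, exact for regions shorter than the bin
count), optionally min-max rescale each region to [0, 1] (for comparing
antibodies of different dynamic range), and summarize each bin across
regions with a two-sided trimmed mean, trim = 0.3 per tail (R's
`mean(trim=)` convention: `floor(0.3 n)` values dropped from each end).

# Half-life estimation

First-order decay of the conversion rate, `r(t) = r0 * 2^(-t/T)`, is
linearized as `ln r = a - k t` and fitted robustly: iteratively reweighted
least squares with Huber weights, tuning constant 1.345, scale = median
absolute residual / 0.6745, tolerance 1e-8, at most 50 iterations — the
documented defaults of the classic robust linear model, restated so the
fit is reproducible in any language. The implementation is the package's
own; the test suite cross-checks it against `MASS::rlm`. Natural-log
linearization is used internally (display conventions such as log2 axes
shifted by the t = 0 median are plotting concerns; `k` and `t1/2 = ln 2/k`
are base-invariant). When residuals vanish (noiseless data) the MAD scale
is zero; the fit then short-circuits to unit weights, which is the exact
least-squares solution.

Replicates are pooled into one fit by default — the robust loss already
downweights outlier replicates — with a per-replicate mode
(`pool_replicates = FALSE`, median of per-replicate `k`) for comparison.
Genes are first filtered: conversion > 0 in at least 3 replicates at every
condition/timepoint, median conversion at t = 0 positive, and medians
non-increasing (equality allowed) across ordered timepoints in every
condition. After filtering, fits with `k <= 0` are reported with an
undefined half-life rather than clipped, to avoid biasing medians.
Per-condition median summaries use only genes with a defined half-life in
all conditions, so conditions are compared on one shared gene set.

The **buffering statistic** is `delta = l2fc_RNA - l2fc_PRO` per gene.
Under steady state, abundance ~ production x half-life, so a pure
stability change shifts deltas positive by `log2(half-life ratio)` while
pure transcriptional changes cancel. Fold changes come from spike-scaled
mean counts with a pseudocount of 1 (`normalized_l2fc()`); shrinkage-based
differential testing is deliberately not reimplemented.

# The synthetic world

The generator states one fixed world (changing it invalidates the
recovery tests' meaning):

| parameter | default | why |
|---|---|---|
| washout timepoints | 0, 10, 25, 40 min | the time course design |
| chase timepoints | 0, 6, 12 h | the labeling design |
| replicates | 6 | the decay experiment design |
| elongation rates | U(1.5, 4.5) kb/min | observed mammalian Pol II range |
| half-lives | log-normal, median 5 h, sdlog 0.5 | mammalian mRNA turnover |
| initial conversion rate | U(0.005, 0.05) | post-pulse conversion levels |
| conversion noise | sigma = 0.1 (log-normal) | replicate scatter |
| depth | 1e7 reads/track | realistic PRO-seq library |
| signal:background | 10:1 | residual t=0 signal and paused peak |
| gene separation | >= 10 kb | unambiguous upstream-TSS annotation |

DRB tracks are per-base Poisson on a density (5'-end counts only, no read
lengths): a wave component uniform over `[TSS, TSS + v t]` clipped at the
gene end, plus a time-independent background (uniform low rate over the
gene and a 250 bp paused promoter peak) that *is* the t = 0 track — the
subtraction step needs a baseline to be meaningful. The per-base wave rate
is derived from `depth` at the latest timepoint; at the default it is
around 0.4-0.5 reads/bp, the regime where the 25% covered-base tile filter
separates wave from background (background coverage ~4-5% of bases fails
it; wave coverage ~35-40% passes).

What the generator does **not** emulate: mappability gaps, overlapping and
nested genes, intron/exon structure, enhancer transcription, termination
read-through, variable per-gene expression in the DRB tracks, lag between
washout and release, and library-specific biases. A green recovery test
establishes that the algorithms invert the generative model stated above —
not that they are robust to every artifact of real data.

# Numerical choices and edge cases

* Negative values after t0 subtraction are censored to 0 (the source is
  silent; covered-base counting requires non-negativity).
* Smoothing applies to covered-base counts only, never signal sums; both
  raw and smoothed counts are kept for audit.
* Degenerate inputs error loudly: zero spike counts name the sample,
  single-timepoint decay designs are rejected, malformed TSV rows are
  reported with their line number.
* Determinism: all generators draw under `withr::with_seed`, so a fixed
  `sim_config` reproduces outputs byte-identically; pipeline manifests
  carry md5 checksums of inputs and parameter dumps.
* Simulation scale in the shipped tests is reduced (e.g. 100-200 genes,
  1e6-1e7 reads) to keep the default test run within desk budgets; the
  statistical margins in the assertions account for the smaller n.

# Limitations

Elongation-rate estimates inherit the 1 kb tile resolution; rates at
t = 10 min for slow genes (< 1.5 kb/min) are near the 3 kb minimum region
length and may be censored. The wave caller assumes non-overlapping
same-strand genes; head-to-head overlap is handled only via strand
separation. The decay model is single-exponential; multi-phase decay or
re-synthesis during the chase will be fitted to an effective rate. The
full-scale published medians (elongation rate and half-life per condition)
require the deposited sequencing data and are not recomputable at desk
scale; the package ships the machinery, and its correctness is established
by recovery on the synthetic world instead.
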