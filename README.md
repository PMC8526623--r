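# polkinetics

Kinetics of RNA polymerase II transcription and mRNA turnover from
sequencing data, for researchers who have nascent-transcription (PRO-seq),
ChIP-seq and metabolic-labeling (SLAM-seq style) experiments and want the
derived kinetic quantities:

* **Elongation rate** (kb/min) from a DRB-washout PRO-seq time course.
  After washing out the CDK9 inhibitor DRB, released polymerases advance
  down each gene at velocity *v*; the front of new signal sits at distance
  *v·t* from the TSS. The caller works on censored difference tracks
  (max(0, s_t − s_0)), tiles the genome in 1 kb windows, smooths covered
  bases with max(counts_{n−1}, counts_n), removes tiles under 25% coverage
  or 0.1 summed signal, merges survivors within 4 kb, drops regions under
  3 kb, annotates each region to the closest upstream TSS, and reports
  **rate = leading edge distance / t**.
* **Stalling index** = TSS-region reads / gene-body reads, and
  **processivity index** = log10(distal/proximal gene-body reads).
* **mRNA half-life** from T→C conversion rates during a chase: first-order
  decay r(t) = r₀·2^(−t/T) linearized as ln r = a − k·t and fitted by a
  robust linear model (Huber IRLS, c = 1.345, MAD scale); **t½ = ln 2 / k**.
* **Transcript buffering** = per-gene difference of steady-state (RNA-seq)
  and nascent (PRO-seq) log2 fold changes; positive skew means stability
  changes exceed production changes.
* Supporting machinery: strand-specific 5′-end tracks, spike-in size
  factors with geometric mean 1, ChIP coverage with 200 bp extension and
  censored log2(ChIP+1)/(Input+1) enrichment, promoter/gene-body
  definitions from TSS atlases and transcript models, RPKM expression
  filters, 100-bin trimmed-mean metagene profiles, and a synthetic-data
  generator with known ground truth for every stage.

Input formats: bedGraph (`.plus`/`.minus` pairs for stranded tracks), BED6,
GTF, and TSV tables. Internals are Bioconductor (`GRanges`, run-length
encoded tracks via `IRanges`/`S4Vectors`, I/O via `rtracklayer`).

## Worked example

Simulate a 30-gene DRB washout time course with known per-gene rates, run
the wave caller, and compare:

```r
library(polkinetics)

cfg <- sim_config(seed = 42, n_genes = 30, chrom_length = 6e6,
                  gene_length_range = c(8e4, 1.4e5), depth = 3e6)
ann    <- make_toy_annotation(cfg)
truth  <- make_ground_truth(cfg)                   # rates U(1.5, 4.5) kb/min
tracks <- simulate_drb_timecourse(ann, truth, cfg) # t = 0, 10, 25, 40 min

res <- run_drb_pipeline(list(WT = tracks), ann$tss)
res$medians
#>   condition timepoint n_genes median_rate
#> 1        WT        10      30    2.895600
#> 2        WT        25      30    2.858240
#> 3        WT        40      30    2.521212
```

Per-gene rates are the leading-edge distance divided by washout time:

```r
head(res$rates[res$rates$timepoint == 10,
               c("gene_id", "leading_edge", "distance_from_tss", "rate")], 4)
#>    gene_id leading_edge distance_from_tss   rate
#> 1  gene001        44000             30312 3.0312
#> 4  gene002       256001             42854 4.2854
#> 7  gene003       391001             16963 1.6963
#> 10 gene004       515001             36216 3.6216
```

gene001's wave front sits 30,312 bp past its TSS at t = 10 min, i.e.
3.03 kb/min. Against the planted truth the t = 10 estimates recover with a
median absolute relative error of 1.3% and Spearman correlation 0.998
(tile resolution is 1 kb, so single-gene errors are a few percent). The
t = 40 median dips because fast genes' waves reach their gene ends and the
edge is clipped — visible in real time courses too.

Half-lives from a simulated conversion table, via the same filters and
robust fit used for real tables:

```r
conv <- simulate_conversion_table(truth, cfg)   # 6 replicates, 0/6/12 h
slam <- run_slam_pipeline(conv)
slam$summary
#>   condition n_genes median_half_life
#> 1        WT      30         5.156068

fit <- fit_decay_robust(c(0, 6, 12), c(0.02, 0.01, 0.005))
sprintf("k = %.4f /h, half-life = %.1f h", fit$k, fit$half_life)
#> [1] "k = 0.1155 /h, half-life = 6.0 h"
```

A conversion rate that halves every 6 hours gives exactly t½ = 6 h.

See `vignettes/transcription-kinetics.Rmd` for the models, parameter
semantics, the synthetic world's assumptions, and numerical edge cases.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computations from
scratch on synthetic data — the DRB wave-calling pipeline (simulate →
difference tracks → tiles → regions → rates), the decay pipeline (filters →
robust fits → summary), and the spike-in normalization round trip — then
writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Progress and recovery diagnostics are logged to stderr; `--seed` controls
every source of randomness.
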