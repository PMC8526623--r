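test_that("toy annotation places separated genes with TSS at the 5' end", {
  cfg1 <- sim_config(seed = 2, n_genes = 1, chrom_length = 2e5,
                     gene_length_range = c(1e5, 1e5))
  ann <- make_toy_annotation(cfg1)
  expect_equal(length(ann$transcripts), 1)
  expect_equal(length(ann$tss), 1)
  expect_equal(width(ann$transcripts), 1e5)
  st <- as.character(strand(ann$transcripts))
  tss5 <- if (st == "+") start(ann$transcripts) else end(ann$transcripts)
  if (st == "+") {
    expect_equal(start(ann$tss), tss5)
  } else {
    expect_equal(end(ann$tss), tss5)
  }

  ## determinism: same config -> identical annotation
  expect_identical(make_toy_annotation(cfg1), make_toy_annotation(cfg1))

  ## capacity error when the chromosome cannot hold the genes
  tiny <- sim_config(seed = 2, n_genes = 10, chrom_length = 1e5,
                     gene_length_range = c(5e4, 5e4))
  expect_error(make_toy_annotation(tiny), "too small")
})

test_that("50 simulated genes never overlap (pairwise sweep)", {
  cfg <- sim_config(seed = 9, n_genes = 50, chrom_length = 5e6,
                    gene_length_range = c(2e4, 8e4))
  ann <- make_toy_annotation(cfg)
  tx <- ann$transcripts
  expect_equal(length(tx), 50)
  ## brute-force pairwise overlap check, ignoring strand
  s <- start(tx); e <- end(tx)
  for (i in 1:49) {
    for (j in (i + 1):50) {
      expect_true(e[i] < s[j] - 10000L + 1L || e[j] < s[i] - 10000L + 1L)
    }
  }
})

test_that("DRB waves stay within v*t of the TSS and t0 equals background", {
  cfg <- sim_config(seed = 4, n_genes = 1, chrom_length = 2e5,
                    gene_length_range = c(1e5, 1e5), depth = 5e4,
                    timepoints_min = c(0, 10),
                    signal_to_background = Inf)      # zero background
  ann <- make_toy_annotation(cfg)
  truth <- make_ground_truth(cfg)
  truth$genes$elongation_rate <- 2      # kb/min
  tr <- simulate_drb_timecourse(ann, truth, cfg)

  ## t0 contains only the background component: here, nothing
  expect_equal(track_total(tr[["0"]]), 0)

  ## all t=10 signal within 20 kb of the TSS
  st <- as.character(strand(ann$transcripts))
  tss <- if (st == "+") start(ann$transcripts) else end(ann$transcripts)
  v <- as.numeric(tr[["10"]]$signal[[st]][["chrS"]])
  covered <- which(v > 0)
  expect_gt(length(covered), 0)
  expect_true(all(abs(covered - tss) <= 20000))

  ## with background, the t0 track is reproduced inside every timepoint run
  cfg_bg <- sim_config(seed = 4, n_genes = 2, chrom_length = 5e5,
                       gene_length_range = c(1e5, 1e5), depth = 1e5)
  annb <- make_toy_annotation(cfg_bg)
  truthb <- make_ground_truth(cfg_bg)
  trb <- simulate_drb_timecourse(annb, truthb, cfg_bg)
  trb2 <- simulate_drb_timecourse(annb, truthb, cfg_bg)
  expect_identical(trb, trb2)           # byte-identical determinism
  expect_gt(track_total(trb[["0"]]), 0)

  ## negative timepoint / non-positive rate are domain errors
  cfg_bad <- cfg
  cfg_bad$timepoints_min <- c(0, -5)
  expect_error(simulate_drb_timecourse(ann, truth, cfg_bad), "negative")
  truth_bad <- truth
  truth_bad$genes$elongation_rate <- 0
  expect_error(simulate_drb_timecourse(ann, truth_bad, cfg), "positive")
})

test_that("the empirical wave front advances at the planted velocity", {
  ## 99th percentile of 5'-end offsets at t=10 for v=3.37 kb/min should sit
  ## at 33.7 kb (within 1.5 kb), averaged over repeated seeds
  fronts <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, n_genes = 1, chrom_length = 2e5,
                      gene_length_range = c(1e5, 1e5), depth = 2e4,
                      timepoints_min = c(0, 10), signal_to_background = Inf)
    ann <- make_toy_annotation(cfg)
    truth <- make_ground_truth(cfg)
    truth$genes$elongation_rate <- 3.37
    tr <- simulate_drb_timecourse(ann, truth, cfg)
    st <- as.character(strand(ann$transcripts))
    tss <- if (st == "+") start(ann$transcripts) else end(ann$transcripts)
    v <- as.numeric(tr[["10"]]$signal[[st]][["chrS"]])
    pos <- rep(which(v > 0), v[v > 0])
    unname(quantile(abs(pos - tss), 0.99))
  }, numeric(1))
  expect_lt(abs(mean(fronts) - 33700), 1500)

  ## front position grows linearly in t (regression slope within 5%)
  cfg <- sim_config(seed = 12, n_genes = 1, chrom_length = 5e5,
                    gene_length_range = c(2e5, 2e5), depth = 3e5,
                    timepoints_min = c(0, 5, 10, 20, 30),
                    signal_to_background = Inf)
  ann <- make_toy_annotation(cfg)
  truth <- make_ground_truth(cfg)
  truth$genes$elongation_rate <- 3
  tr <- simulate_drb_timecourse(ann, truth, cfg)
  st <- as.character(strand(ann$transcripts))
  tss <- if (st == "+") start(ann$transcripts) else end(ann$transcripts)
  tps <- c(5, 10, 20, 30)
  front <- vapply(tps, function(t) {
    v <- as.numeric(tr[[as.character(t)]]$signal[[st]][["chrS"]])
    max(abs(which(v > 0) - tss))
  }, numeric(1))
  slope <- coef(lm(front ~ tps))[2] / 1000   # kb/min
  expect_lt(abs(slope - 3) / 3, 0.05)
})

test_that("conversion tables decay exactly at sigma = 0", {
  cfg <- sim_config(seed = 6, n_genes = 3, noise_sigma = 0)
  truth <- make_ground_truth(cfg)
  truth$genes$half_life <- c(6, 6, Inf)
  tab <- simulate_conversion_table(truth, cfg)

  g1 <- tab[tab$gene_id == "gene001", ]
  r0 <- g1$conversion_rate[g1$timepoint_h == 0][1]
  expect_equal(unique(g1$conversion_rate[g1$timepoint_h == 6]), r0 / 2)
  expect_equal(unique(g1$conversion_rate[g1$timepoint_h == 12]), r0 / 4)

  ## infinite half-life -> constant series
  g3 <- tab[tab$gene_id == "gene003", ]
  expect_equal(length(unique(g3$conversion_rate)), 1)

  ## log-linearity: second differences of ln(r) over equal spacing are 0
  lr <- log(vapply(c(0, 6, 12), function(t) {
    g1$conversion_rate[g1$timepoint_h == t][1]
  }, numeric(1)))
  expect_equal(diff(diff(lr)), 0)

  ## determinism with noise
  cfg2 <- sim_config(seed = 6, n_genes = 3, noise_sigma = 0.1)
  expect_identical(simulate_conversion_table(truth, cfg2),
                   simulate_conversion_table(truth, cfg2))
  ## all rates in (0, 1]
  expect_true(all(tab$conversion_rate > 0 & tab$conversion_rate <= 1))
})

test_that("pausing tracks split reads by the planted stalling index", {
  cfg <- sim_config(seed = 8, n_genes = 4, chrom_length = 1e6,
                    gene_length_range = c(4e4, 6e4), depth = 4e5)
  ann <- make_toy_annotation(cfg)
  truth <- make_ground_truth(cfg)
  truth$genes$stalling_index <- c(1, 1, 0, 2)
  tr <- simulate_pausing_tracks(ann, truth, cfg)
  expect_identical(tr, simulate_pausing_tracks(ann, truth, cfg))

  prom <- make_promoters(ann$tss)
  tx <- ann$transcripts
  st <- as.character(strand(tx))
  body <- GRanges("chrS", IRanges(
    ifelse(st == "+", end(prom) + 1L, start(tx)),
    ifelse(st == "+", end(tx), start(prom) - 1L)), st,
    seqlengths = ann$seqlengths)
  pc <- region_signal(tr, prom)
  bc <- region_signal(tr, body)

  ## SI = 0: body-only mode, no promoter reads
  expect_equal(pc[3], 0)

  ## SI = 1 genes: promoter/body ratio within 3 binomial SE of 1
  for (g in c(1, 2, 4)) {
    si <- truth$genes$stalling_index[g]
    n <- pc[g] + bc[g]
    p <- si / (1 + si)
    se_ratio <- sqrt(p * (1 - p) / n) / (1 - p)^2
    expect_lt(abs(pc[g] / bc[g] - si), 3 * se_ratio)
  }
})

test_that("spike-in counts encode the planted size factors", {
  cfg <- sim_config(seed = 10, depth = 1e6)
  truth <- make_ground_truth(cfg, size_factors = c(1, 2, 0.5))
  mats <- simulate_spikein_counts(truth, cfg)
  expect_identical(mats, simulate_spikein_counts(truth, cfg))

  f <- compute_spikein_factors(colSums(mats$target), colSums(mats$spike))
  expect_equal(unname(f), c(1, 2, 0.5), tolerance = 0.02)

  ## equal planted factors -> roughly equal spike totals
  truth1 <- make_ground_truth(cfg, size_factors = c(1, 1, 1))
  m1 <- simulate_spikein_counts(truth1, cfg)
  tot <- colSums(m1$spike)
  expect_lt(diff(range(tot)) / mean(tot), 0.05)
})
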