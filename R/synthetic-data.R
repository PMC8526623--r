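#' Configuration of the synthetic-data generator
#'
#' Collects the experimental-design constants emulated by the generator:
#' washout timepoints 0/10/25/40 min for the DRB time course, chase
#' timepoints 0/6/12 h with 6 replicates for the metabolic-labeling decay
#' tables, and a fixed fraction of reads assigned to an exogenous spike-in
#' genome. `depth` is the expected number of target-genome reads in the
#' densest track (the latest washout timepoint).
#'
#' @param seed integer RNG seed; a fixed seed makes every generator output
#'   byte-identical
#' @param n_genes number of genes
#' @param chrom_length chromosome length in bp
#' @param gene_length_range min/max gene length in bp
#' @param timepoints_min DRB washout timepoints in minutes (must include 0)
#' @param slam_timepoints_h chase timepoints in hours (must include 0)
#' @param n_replicates replicates per condition/timepoint in decay tables
#' @param depth expected reads per track
#' @param noise_sigma sd of the multiplicative log-normal noise on
#'   conversion rates
#' @param spike_fraction fraction of reads from the spike-in genome, in
#'   \[0, 1\]
#' @param signal_to_background ratio of per-base wave rate to background
#'   rate; `Inf` means background-free tracks
#' @param tss_width width of the simulated TSS regions in bp
#' @param min_gene_gap minimum gap between genes in bp (>= 10 kb keeps
#'   upstream-TSS annotation unambiguous)
#' @return a list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, chrom_length = 2e6,
                       gene_length_range = c(2e4, 1e5),
                       timepoints_min = c(0, 10, 25, 40),
                       slam_timepoints_h = c(0, 6, 12),
                       n_replicates = 6L, depth = 1e7, noise_sigma = 0.1,
                       spike_fraction = 0.1, signal_to_background = 10,
                       tss_width = 10L, min_gene_gap = 1e4) {
  check_that(n_genes >= 1L, "need at least one gene")
  check_that(length(gene_length_range) == 2L &&
             gene_length_range[1L] <= gene_length_range[2L] &&
             gene_length_range[2L] <= chrom_length,
             "gene_length_range must fit in the chromosome")
  check_that(0 %in% timepoints_min && all(timepoints_min >= 0),
             "timepoints_min must include 0 and be non-negative")
  check_that(0 %in% slam_timepoints_h && all(slam_timepoints_h >= 0),
             "slam_timepoints_h must include 0 and be non-negative")
  check_that(spike_fraction >= 0 && spike_fraction <= 1,
             "spike_fraction must be in [0, 1]")
  check_that(noise_sigma >= 0, "noise_sigma must be >= 0")
  check_that(depth > 0 && signal_to_background > 0, "rates must be positive")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 chrom_length = as.integer(chrom_length),
                 gene_length_range = gene_length_range,
                 timepoints_min = sort(timepoints_min),
                 slam_timepoints_h = sort(slam_timepoints_h),
                 n_replicates = as.integer(n_replicates), depth = depth,
                 noise_sigma = noise_sigma, spike_fraction = spike_fraction,
                 signal_to_background = signal_to_background,
                 tss_width = as.integer(tss_width),
                 min_gene_gap = as.integer(min_gene_gap)),
            class = "sim_config")
}

#' Ground-truth kinetic parameters for a simulation
#'
#' Draws per-gene elongation rates (uniform, default 1.5-4.5 kb/min, the
#' range of observed mammalian Pol II speeds), stalling indices and mRNA
#' half-lives (log-normal; the half-life median of 5 h matches typical
#' mammalian mRNA turnover) plus per-sample spike-in size factors.
#'
#' @param cfg a [sim_config()]
#' @param rate_range elongation-rate range in kb/min
#' @param stalling_meanlog,stalling_sdlog log-normal stalling-index law
#' @param half_life_meanlog,half_life_sdlog log-normal half-life law (hours)
#' @param n_samples number of samples carrying size factors
#' @param size_factors optional planted size factors (geometric mean should
#'   be 1 for exact recovery); drawn log-normally and rescaled if `NULL`
#' @return list of class `ground_truth` with `genes` (data.frame:
#'   `gene_id`, `elongation_rate`, `stalling_index`, `half_life`) and
#'   `size_factors`
#' @export
make_ground_truth <- function(cfg, rate_range = c(1.5, 4.5),
                              stalling_meanlog = log(2),
                              stalling_sdlog = 0.5,
                              half_life_meanlog = log(5),
                              half_life_sdlog = 0.5,
                              n_samples = 3L, size_factors = NULL) {
  withr::with_seed(cfg$seed + 1L, {
    genes <- data.frame(
      gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
      elongation_rate = stats::runif(cfg$n_genes, rate_range[1L],
                                     rate_range[2L]),
      stalling_index = stats::rlnorm(cfg$n_genes, stalling_meanlog,
                                     stalling_sdlog),
      half_life = stats::rlnorm(cfg$n_genes, half_life_meanlog,
                                half_life_sdlog))
    if (is.null(size_factors)) {
      sf <- stats::rlnorm(n_samples, 0, 0.3)
      size_factors <- sf / geom_mean(sf)
    }
  })
  check_that(all(size_factors > 0), "size factors must be positive")
  structure(list(genes = genes, size_factors = size_factors),
            class = "ground_truth")
}

#' Toy annotation: non-overlapping genes on one chromosome
#'
#' Places `n_genes` genes left to right on a single chromosome (`chrS`),
#' separated by at least `min_gene_gap` bp regardless of strand so that
#' closest-upstream-TSS annotation is unambiguous. Strands are drawn
#' uniformly. Each gene gets one transcript and one TSS region of
#' `tss_width` bp at its strand-aware 5' end.
#'
#' @param cfg a [sim_config()]
#' @return list with `transcripts` (`GRanges`: `gene_id`, `transcript_id`),
#'   `tss` (`GRanges`: `gene_id`), and `seqlengths`
#' @export
make_toy_annotation <- function(cfg) {
  withr::with_seed(cfg$seed, {
    len <- round(stats::runif(cfg$n_genes, cfg$gene_length_range[1L],
                              cfg$gene_length_range[2L]))
    gap <- round(stats::runif(cfg$n_genes, cfg$min_gene_gap,
                              1.5 * cfg$min_gene_gap))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  })
  starts <- cumsum(gap) + cumsum(c(0, len[-cfg$n_genes]))
  ends <- starts + len - 1L
  if (ends[cfg$n_genes] + cfg$min_gene_gap > cfg$chrom_length) {
    stop(sprintf(paste0("chromosome too small: need >= %d bp for %d genes ",
                        "(have %d)"),
                 ends[cfg$n_genes] + cfg$min_gene_gap, cfg$n_genes,
                 cfg$chrom_length), call. = FALSE)
  }
  sl <- c(chrS = cfg$chrom_length)
  gid <- sprintf("gene%03d", seq_len(cfg$n_genes))
  tx <- GenomicRanges::GRanges("chrS", IRanges::IRanges(starts, ends),
                               strand, seqlengths = sl,
                               gene_id = gid,
                               transcript_id = paste0(gid, ".t1"))
  tss_s <- ifelse(strand == "+", starts, ends - cfg$tss_width + 1L)
  tss <- GenomicRanges::GRanges("chrS",
                                IRanges::IRanges(tss_s,
                                                 width = cfg$tss_width),
                                strand, seqlengths = sl, gene_id = gid)
  list(transcripts = tx, tss = tss, seqlengths = sl)
}

## strand-aware TSS point of each transcript (the wave launch site)
.tss_point <- function(transcripts) {
  st <- as.character(GenomicRanges::strand(transcripts))
  ifelse(st == "+", GenomicRanges::start(transcripts),
         GenomicRanges::end(transcripts))
}

## build a stranded SignalTrack from 5'-end positions (integer vectors)
.positions_track <- function(pos_plus, pos_minus, seqlengths,
                             units = "read 5' ends") {
  chrom <- names(seqlengths)[1L]
  one <- function(p) {
    cnt <- tabulate(p, nbins = seqlengths[[1L]])
    out <- list(S4Vectors::Rle(cnt))
    names(out) <- chrom
    methods::as(out, "RleList")
  }
  SignalTrack(list("+" = one(pos_plus), "-" = one(pos_minus)), units = units)
}

#' Simulate a DRB-washout PRO-seq time course
#'
#' At washout time `t`, each gene receives read 5' ends uniformly over
#' `[TSS, TSS + v_g * t * 1000]` bp (clipped to the gene end) — the
#' advancing wave — on top of a time-independent background component:
#' uniform low-rate signal over the gene plus a promoter-proximal paused
#' peak. The `t = 0` track contains exactly the background component; all
#' counts are per-base Poisson, strand-specific. The per-base wave and
#' background rates are set so the latest timepoint totals about
#' `cfg$depth` reads with a wave:background rate ratio of
#' `cfg$signal_to_background` (`Inf` disables the background entirely).
#'
#' @param ann annotation from [make_toy_annotation()]
#' @param truth a [make_ground_truth()] object (elongation rates, kb/min)
#' @param cfg a [sim_config()]
#' @return named list of stranded `SignalTrack`s, one per timepoint (names
#'   are the minutes, e.g. `"0"`, `"10"`)
#' @export
simulate_drb_timecourse <- function(ann, truth, cfg) {
  v <- truth$genes$elongation_rate
  check_that(length(v) == length(ann$transcripts),
             "need an elongation rate for every gene")
  check_that(all(v > 0), "elongation rates must be positive")
  tps <- cfg$timepoints_min
  check_that(all(tps >= 0), "negative timepoint")
  tx <- ann$transcripts
  st <- as.character(GenomicRanges::strand(tx))
  L <- GenomicRanges::width(tx)
  tss <- .tss_point(tx)
  peak_w <- 250L
  wave_len <- function(t) pmin(round(v * t * 1000), L)
  s2b <- cfg$signal_to_background
  denom <- sum(wave_len(max(tps))) +
    (if (is.finite(s2b)) length(v) * peak_w + sum(L) / s2b else 0)
  lambda_w <- cfg$depth / denom
  lambda_b <- if (is.finite(s2b)) lambda_w / s2b else 0

  ## uniform positions over [a, a + n_bases - 1] in transcription direction
  draw <- function(a, n_bases, rate, dir) {
    n <- stats::rpois(1L, rate * n_bases)
    off <- sample.int(n_bases, n, replace = TRUE) - 1L
    if (dir == "+") a + off else a - off
  }

  gather <- function(lst, plus) {
    keep <- if (plus) st == "+" else st == "-"
    out <- if (!any(keep)) NULL else unlist(lst[keep], use.names = FALSE)
    if (is.null(out)) integer(0) else out
  }
  withr::with_seed(cfg$seed + 11L, {
    bg <- vector("list", length(v))
    if (lambda_b > 0) {
      for (g in seq_along(v)) {
        bg[[g]] <- c(draw(tss[g], L[g], lambda_b, st[g]),    # residual body
                     draw(tss[g], peak_w, lambda_w, st[g]))  # paused peak
      }
    }
    bg_plus <- gather(bg, TRUE); bg_minus <- gather(bg, FALSE)
    tracks <- list()
    for (t in tps) {
      if (t == 0) {
        tracks[[as.character(t)]] <-
          .positions_track(bg_plus, bg_minus, ann$seqlengths)
        next
      }
      wl <- wave_len(t)
      wv <- vector("list", length(v))
      for (g in seq_along(v)) {
        wv[[g]] <- draw(tss[g], wl[g], lambda_w, st[g])
      }
      tracks[[as.character(t)]] <-
        .positions_track(c(bg_plus, gather(wv, TRUE)),
                         c(bg_minus, gather(wv, FALSE)), ann$seqlengths)
    }
    tracks
  })
}

#' Simulate promoter-paused PRO-seq tracks
#'
#' Per gene, `depth / n_genes` expected reads are split between the
#' promoter (TSS region extended by +/- 250 bp, the standard promoter
#' definition) and a uniform gene body such that the expected
#' promoter:body count ratio equals the gene's planted stalling index. A
#' stalling index of 0 puts all reads in the body.
#'
#' @param ann annotation from [make_toy_annotation()]
#' @param truth a [make_ground_truth()] with non-negative stalling indices
#' @param cfg a [sim_config()]
#' @return a stranded `SignalTrack` of 5'-end counts
#' @export
simulate_pausing_tracks <- function(ann, truth, cfg) {
  si <- truth$genes$stalling_index
  check_that(length(si) == length(ann$transcripts),
             "need a stalling index for every gene")
  check_that(all(si >= 0), "stalling indices must be non-negative")
  prom <- make_promoters(ann$tss)
  tx <- ann$transcripts
  st <- as.character(GenomicRanges::strand(tx))
  body_s <- ifelse(st == "+", GenomicRanges::end(prom) + 1L,
                   GenomicRanges::start(tx))
  body_e <- ifelse(st == "+", GenomicRanges::end(tx),
                   GenomicRanges::start(prom) - 1L)
  check_that(all(body_s <= body_e), "gene too short for a body region")
  withr::with_seed(cfg$seed + 21L, {
    pp <- integer(0); pm <- integer(0)
    for (g in seq_along(si)) {
      n <- stats::rpois(1L, cfg$depth / cfg$n_genes)
      np <- stats::rbinom(1L, n, si[g] / (1 + si[g]))
      pos <- c(GenomicRanges::start(prom)[g] - 1L +
                 sample.int(GenomicRanges::width(prom)[g], np, replace = TRUE),
               body_s[g] - 1L +
                 sample.int(body_e[g] - body_s[g] + 1L, n - np,
                            replace = TRUE))
      if (st[g] == "+") pp <- c(pp, pos) else pm <- c(pm, pos)
    }
    .positions_track(pp, pm, ann$seqlengths)
  })
}

#' Simulate a decaying T-to-C conversion-rate table
#'
#' Per gene, replicate and chase timepoint `t` (hours), the conversion rate
#' is `r0 * 2^(-t / T) * exp(eps)` with `eps ~ N(0, sigma^2)` and the
#' initial rate `r0` drawn uniformly in (0.005, 0.05), the realistic range
#' after a saturating labeling pulse; values are capped at 1.
#'
#' @param truth a [make_ground_truth()] (half-lives `T` in hours, > 0;
#'   `Inf` gives a constant series)
#' @param cfg a [sim_config()]
#' @param conditions condition labels; all share the truth half-lives
#' @return data.frame: `gene_id`, `condition`, `replicate`, `timepoint_h`,
#'   `conversion_rate`
#' @export
simulate_conversion_table <- function(truth, cfg, conditions = "WT") {
  Th <- truth$genes$half_life
  check_that(all(Th > 0), "half-lives must be positive")
  n <- nrow(truth$genes)
  withr::with_seed(cfg$seed + 31L, {
    r0 <- stats::runif(n, 0.005, 0.05)
    grid <- expand.grid(gene = seq_len(n), condition = conditions,
                        replicate = seq_len(cfg$n_replicates),
                        timepoint_h = cfg$slam_timepoints_h,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    eps <- stats::rnorm(nrow(grid), 0, cfg$noise_sigma)
  })
  rate <- pmin(r0[grid$gene] * 2^(-grid$timepoint_h / Th[grid$gene]) *
                 exp(eps), 1)
  out <- data.frame(gene_id = truth$genes$gene_id[grid$gene],
                    condition = grid$condition, replicate = grid$replicate,
                    timepoint_h = grid$timepoint_h, conversion_rate = rate)
  out[order(out$gene_id, out$condition, out$timepoint_h, out$replicate), ,
      drop = FALSE]
}

#' Simulate target and spike-in count matrices
#'
#' Spike-in totals per sample are proportional to `1 / size_factor` (a
#' sample with a larger planted factor recovered less spike-in material),
#' so spike-ratio scaling by [compute_spikein_factors()] recovers the
#' planted factors. Target counts are Poisson around fixed per-gene means.
#'
#' @param truth a [make_ground_truth()] carrying positive `size_factors`
#' @param cfg a [sim_config()]; `depth` and `spike_fraction` set expected
#'   totals
#' @param n_target_genes,n_spike_genes matrix sizes
#' @return list with `target` and `spike` count matrices (genes x samples)
#' @export
simulate_spikein_counts <- function(truth, cfg, n_target_genes = 200L,
                                    n_spike_genes = 50L) {
  sf <- truth$size_factors
  check_that(all(sf > 0), "size factors must be positive")
  ns <- length(sf)
  withr::with_seed(cfg$seed + 41L, {
    wt <- stats::rgamma(n_target_genes, shape = 1)
    wt <- wt / sum(wt) * cfg$depth * (1 - cfg$spike_fraction)
    ws <- stats::rgamma(n_spike_genes, shape = 1)
    ws <- ws / sum(ws) * cfg$depth * cfg$spike_fraction
    target <- matrix(stats::rpois(n_target_genes * ns, rep(wt, ns)),
                     ncol = ns)
    spike <- matrix(stats::rpois(n_spike_genes * ns,
                                 rep(ws, ns) / rep(sf, each = n_spike_genes)),
                    ncol = ns)
  })
  sample_names <- sprintf("sample%d", seq_len(ns))
  dimnames(target) <- list(sprintf("tgene%03d", seq_len(n_target_genes)),
                           sample_names)
  dimnames(spike) <- list(sprintf("sgene%03d", seq_len(n_spike_genes)),
                          sample_names)
  list(target = target, spike = spike)
}
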