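#' Parameters of the leading-edge wave caller
#'
#' Defaults follow the published heuristic: 1 kb non-overlapping tiles,
#' tiles with less than 25% of bases covered or a summed normalized signal
#' below 0.1 removed, retained tiles merged within 4 kb, and regions shorter
#' than 3 kb discarded. Thresholds are inclusive on the keep side
#' (`>= 0.25`, `>= 0.1`, gap `<= 4000`, length `>= 3000`).
#'
#' @param tile tile width in bp
#' @param min_covered_frac minimum fraction of covered bases per tile
#' @param min_tile_signal minimum summed signal per tile
#' @param merge_gap maximum gap in bp merged between retained tiles
#' @param min_region_len minimum region length in bp
#' @return a list of class `wave_params`
#' @export
wave_params <- function(tile = 1000L, min_covered_frac = 0.25,
                        min_tile_signal = 0.1, merge_gap = 4000L,
                        min_region_len = 3000L) {
  check_that(tile > 0 && min_tile_signal > 0 && merge_gap > 0 &&
             min_region_len > 0, "wave parameters must be positive")
  check_that(min_covered_frac > 0 && min_covered_frac <= 1,
             "min_covered_frac must be in (0, 1]")
  structure(list(tile = as.integer(tile),
                 min_covered_frac = min_covered_frac,
                 min_tile_signal = min_tile_signal,
                 merge_gap = as.integer(merge_gap),
                 min_region_len = as.integer(min_region_len)),
            class = "wave_params")
}

#' Censored difference track between a washout timepoint and t = 0
#'
#' Per base, `max(0, s_t - s_0)`. Subtracting the residual t = 0 signal
#' prevents merging waves with the standing signal of genes in head-to-tail
#' orientation; negatives are censored to zero so covered-base counting
#' stays meaningful.
#'
#' @param track_t,track_0 `SignalTrack`s with identical strands/chromosomes
#' @return a `SignalTrack` of non-negative differences
#' @export
difference_track <- function(track_t, track_0) {
  check_that(identical(names(track_t$signal), names(track_0$signal)),
             "tracks differ in strandedness")
  check_that(identical(track_t$seqlengths, track_0$seqlengths),
             "tracks differ in chromosomes")
  out <- track_map(function(a, b) pmax(a - b, 0), track_t, track_0)
  out$units <- paste0("diff(", track_t$units, ")")
  out
}

#' Tile a track and smooth covered-base counts
#'
#' Splits every chromosome/strand into non-overlapping tiles (the last,
#' partial tile is kept and clipped), counting covered bases (signal > 0)
#' and summing signal per tile. Covered-base counts are then smoothed
#' non-iteratively as `smoothed_n = max(raw_{n-1}, raw_n)` computed from the
#' raw vector, with `smoothed_1 = raw_1`; "preceding" means the lower
#' genomic coordinate on both strands. Signal sums are left unsmoothed; both
#' raw and smoothed covered counts are returned for audit.
#'
#' @param track a `SignalTrack`
#' @param params a [wave_params()] list
#' @return data.frame: `chrom`, `strand`, `start`, `end` (1-based, closed),
#'   `covered`, `smoothed_covered`, `signal_sum`
#' @export
tile_and_smooth <- function(track, params = wave_params()) {
  w <- params$tile
  out <- list()
  for (st in names(track$signal)) {
    for (ch in names(track$signal[[st]])) {
      rle <- track$signal[[st]][[ch]]
      L <- length(rle)
      n <- as.integer(ceiling(L / w))
      starts <- seq.int(1L, by = w, length.out = n)
      ends <- pmin(starts + w - 1L, L)
      v <- IRanges::Views(rle, start = starts, end = ends)
      sums <- IRanges::viewSums(v)
      cov <- IRanges::viewSums(IRanges::Views((rle > 0) * 1L,
                                              start = starts, end = ends))
      sm <- pmax(c(cov[1L], cov[-n]), cov)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, strand = st, start = starts, end = ends,
        covered = as.numeric(cov), smoothed_covered = as.numeric(sm),
        signal_sum = as.numeric(sums))
    }
  }
  do.call(rbind, out)
}

#' Call contiguously expressed regions from filtered tiles
#'
#' Retains tiles with `smoothed_covered >= min_covered_frac * tile` and
#' `signal_sum >= min_tile_signal`, merges retained tiles whose gap is at
#' most `merge_gap` bp into regions (gap bases included in the region span),
#' and drops regions shorter than `min_region_len` bp.
#'
#' @param tiles data.frame from [tile_and_smooth()]
#' @param params a [wave_params()] list
#' @return `GRanges` of expressed regions with strand
#' @export
call_expressed_regions <- function(tiles, params = wave_params()) {
  keep <- tiles$smoothed_covered >= params$min_covered_frac * params$tile &
    tiles$signal_sum >= params$min_tile_signal
  kt <- tiles[keep, , drop = FALSE]
  if (nrow(kt) == 0L) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(kt$chrom, IRanges::IRanges(kt$start, kt$end),
                               kt$strand)
  ## reduce() with min.gapwidth = merge_gap + 1 merges gaps <= merge_gap
  reg <- GenomicRanges::reduce(gr, min.gapwidth = params$merge_gap + 1L)
  reg[GenomicRanges::width(reg) >= params$min_region_len]
}

#' Annotate expressed regions to the closest upstream TSS
#'
#' For each region, picks the same-strand TSS whose position (strand-aware
#' 5' point of the TSS range) is closest upstream of the region's anchor
#' boundary. With the default `anchor = "end"` the anchor is the region's
#' strand-aware 3' (leading-edge) boundary, so a TSS lying inside the region
#' is eligible — regions are tile-quantized and typically begin slightly
#' upstream of the TSS that launched them. `anchor = "start"` restricts to
#' TSS at or upstream of the region's 5' boundary. Regions with no eligible
#' upstream TSS are dropped.
#'
#' @param regions stranded `GRanges` of expressed regions
#' @param tss stranded `GRanges` with a `gene_id` metadata column
#' @param anchor `"end"` (default) or `"start"`
#' @return `regions` subset with `gene_id` and `tss_pos` metadata columns
#' @export
annotate_to_upstream_tss <- function(regions, tss, anchor = c("end", "start")) {
  anchor <- match.arg(anchor)
  check_that(length(tss) > 0L, "TSS set is empty")
  gid <- S4Vectors::mcols(tss)$gene_id
  check_that(!is.null(gid), "tss needs a gene_id column")
  tst <- as.character(GenomicRanges::strand(tss))
  tpos <- ifelse(tst == "+", GenomicRanges::start(tss),
                 GenomicRanges::end(tss))
  rst <- as.character(GenomicRanges::strand(regions))
  rch <- as.character(GenomicRanges::seqnames(regions))
  tch <- as.character(GenomicRanges::seqnames(tss))
  n <- length(regions)
  gene <- rep(NA_character_, n)
  pos <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- which(tch == rch[i] & tst == rst[i])
    if (!length(j)) next
    if (rst[i] == "+") {
      bound <- if (anchor == "end") GenomicRanges::end(regions)[i] else
        GenomicRanges::start(regions)[i]
      j <- j[tpos[j] <= bound]
      if (!length(j)) next
      k <- j[which.max(tpos[j])]
    } else {
      bound <- if (anchor == "end") GenomicRanges::start(regions)[i] else
        GenomicRanges::end(regions)[i]
      j <- j[tpos[j] >= bound]
      if (!length(j)) next
      k <- j[which.min(tpos[j])]
    }
    gene[i] <- gid[k]
    pos[i] <- tpos[k]
  }
  out <- regions[!is.na(gene)]
  S4Vectors::mcols(out)$gene_id <- gene[!is.na(gene)]
  S4Vectors::mcols(out)$tss_pos <- pos[!is.na(gene)]
  out
}

#' Per-gene elongation rates from wave leading edges
#'
#' For each gene, condition and washout timepoint, the leading edge is the
#' strand-aware 3'-most boundary over the gene's assigned regions; the
#' elongation rate is the TSS-to-edge distance divided by the time after
#' washout, in kb/min. Only genes whose expressed region is defined at every
#' (condition, timepoint) enter the table; genes with a non-positive
#' TSS-to-edge distance anywhere are flagged and excluded.
#'
#' @param regions annotated `GRanges` (from [annotate_to_upstream_tss()])
#'   with `gene_id`, `tss_pos`, and `condition` / `timepoint` metadata
#'   columns (minutes after washout, > 0)
#' @return list with `rates` (data.frame: `gene_id`, `condition`,
#'   `timepoint`, `leading_edge`, `distance_from_tss`, `rate`) and
#'   `excluded` (data.frame: `gene_id`, `reason`)
#' @export
elongation_rates <- function(regions) {
  mc <- S4Vectors::mcols(regions)
  check_that(all(c("gene_id", "tss_pos", "condition", "timepoint") %in%
                 colnames(mc)), "regions lack required metadata columns")
  tp <- mc$timepoint
  check_that(all(tp > 0), "timepoints must be positive (exclude t = 0)")
  st <- as.character(GenomicRanges::strand(regions))
  edge <- ifelse(st == "+", GenomicRanges::end(regions),
                 GenomicRanges::start(regions))
  dist <- ifelse(st == "+", edge - mc$tss_pos, mc$tss_pos - edge)
  df <- data.frame(gene_id = mc$gene_id, condition = mc$condition,
                   timepoint = tp, leading_edge = edge,
                   distance_from_tss = dist)
  ## one row per gene x condition x timepoint: 3'-most edge
  pick <- order(df$gene_id, df$condition, df$timepoint, -df$distance_from_tss)
  df <- df[pick, , drop = FALSE]
  df <- df[!duplicated(df[c("gene_id", "condition", "timepoint")]), ,
           drop = FALSE]
  combos <- unique(df[c("condition", "timepoint")])
  n_required <- nrow(combos)
  cnt <- table(df$gene_id)
  complete <- names(cnt)[cnt == n_required]
  flagged <- unique(df$gene_id[df$distance_from_tss <= 0])
  excl_row <- function(ids, why) {
    data.frame(gene_id = ids, reason = rep(why, length(ids)))
  }
  excluded <- rbind(
    excl_row(setdiff(unique(df$gene_id), complete),
             "missing at some condition/timepoint"),
    excl_row(flagged, "non-positive TSS distance"))
  df <- df[df$gene_id %in% setdiff(complete, flagged), , drop = FALSE]
  df$rate <- df$distance_from_tss / (df$timepoint * 1000)
  rownames(df) <- NULL
  list(rates = df, excluded = excluded)
}

#' Per-condition median elongation rates
#'
#' @param rates the `rates` data.frame from [elongation_rates()]
#' @param genes optional gene subset (e.g. genes longer than 100 kb)
#' @return data.frame: `condition`, `timepoint`, `n_genes`, `median_rate`
#' @export
median_rates <- function(rates, genes = NULL) {
  if (!is.null(genes)) rates <- rates[rates$gene_id %in% genes, , drop = FALSE]
  sp <- split(rates, list(rates$condition, rates$timepoint), drop = TRUE)
  out <- lapply(sp, function(d) data.frame(
    condition = d$condition[1L], timepoint = d$timepoint[1L],
    n_genes = nrow(d), median_rate = stats::median(d$rate)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$timepoint), , drop = FALSE]
}

#' Processivity index of a gene body
#'
#' `log10(distal / proximal)` read counts, where the proximal and distal
#' windows are the first and last fractions of the gene body in
#' transcription direction (both default to 10%). Zero proximal reads yield
#' `NA` with a flag.
#'
#' @param track a `SignalTrack`
#' @param gene_body stranded `GRanges` (one or more gene bodies)
#' @param proximal_frac,distal_frac window fractions in (0, 0.5]
#' @return data.frame: `proximal`, `distal`, `index`, `flag`
#' @export
processivity_index <- function(track, gene_body, proximal_frac = 0.1,
                               distal_frac = 0.1) {
  check_that(proximal_frac > 0 && proximal_frac <= 0.5 &&
             distal_frac > 0 && distal_frac <= 0.5,
             "window fractions must be in (0, 0.5]")
  wl <- GenomicRanges::width(gene_body)
  pw <- pmax(1L, as.integer(floor(wl * proximal_frac)))
  dw <- pmax(1L, as.integer(floor(wl * distal_frac)))
  st <- as.character(GenomicRanges::strand(gene_body))
  s <- GenomicRanges::start(gene_body)
  e <- GenomicRanges::end(gene_body)
  prox <- GenomicRanges::GRanges(GenomicRanges::seqnames(gene_body),
    IRanges::IRanges(ifelse(st == "+", s, e - pw + 1L),
                     ifelse(st == "+", s + pw - 1L, e)), st)
  dist <- GenomicRanges::GRanges(GenomicRanges::seqnames(gene_body),
    IRanges::IRanges(ifelse(st == "+", e - dw + 1L, s),
                     ifelse(st == "+", e, s + dw - 1L)), st)
  p <- region_signal(track, prox)
  d <- region_signal(track, dist)
  idx <- ifelse(p > 0, log10(d / p), NA_real_)
  data.frame(proximal = p, distal = d, index = idx,
             flag = ifelse(p > 0, "", "zero_proximal"))
}
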