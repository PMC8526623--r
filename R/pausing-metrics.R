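#' Pol II stalling index
#'
#' Ratio of TSS-region (promoter) reads to gene-body reads; elevated values
#' indicate promoter-proximal polymerase accumulation. The ratio is
#' scale-invariant within a sample, so raw and spike-normalized counts give
#' the same index as long as both regions share the scaling.
#'
#' @param promoter_count,body_count non-negative read counts (vectorized)
#' @return numeric vector; `NA` (flagged by warning) where `body_count == 0`
#' @export
stalling_index <- function(promoter_count, body_count) {
  check_that(all(promoter_count >= 0) && all(body_count >= 0),
             "counts must be non-negative")
  bad <- body_count == 0
  if (any(bad)) warning(sprintf("%d gene(s) with zero body count: index NA",
                                sum(bad)))
  ifelse(bad, NA_real_, promoter_count / body_count)
}

#' Quantify promoter and gene-body signal per gene
#'
#' Counts track signal over promoters, gene bodies and the read-through
#' control window (the 250 bp window from 500 to 250 bp upstream of the
#' promoter's strand-aware 5' boundary), and converts to RPKM.
#'
#' @param track a `SignalTrack`
#' @param promoters,bodies stranded `GRanges` with `gene_id` metadata, in
#'   matching gene order
#' @param library_size mapped reads for the RPKM denominator
#' @return data.frame: `gene_id`, `promoter_count`, `body_count`,
#'   `upstream_count`, `promoter_rpkm`, `body_rpkm`, `upstream_rpkm`
#' @export
quantify_genes <- function(track, promoters, bodies, library_size) {
  gid <- S4Vectors::mcols(promoters)$gene_id
  check_that(!is.null(gid), "promoters need a gene_id column")
  check_that(identical(gid, S4Vectors::mcols(bodies)$gene_id),
             "promoters and bodies must list the same genes in order")
  up <- upstream_window(promoters)
  pc <- region_signal(track, promoters)
  bc <- region_signal(track, bodies)
  uc <- region_signal(track, up)
  data.frame(
    gene_id = gid,
    promoter_count = pc, body_count = bc, upstream_count = uc,
    promoter_rpkm = region_rpkm(pc, GenomicRanges::width(promoters),
                                library_size),
    body_rpkm = region_rpkm(bc, GenomicRanges::width(bodies), library_size),
    upstream_rpkm = region_rpkm(uc, GenomicRanges::width(up), library_size))
}

#' Read-through control window upstream of a promoter
#'
#' The 250 bp window starting 500 bp and ending 250 bp upstream of the
#' promoter's strand-aware 5' boundary; high signal here marks genes whose
#' promoter signal may be transcriptional read-through from an upstream
#' gene.
#'
#' @param promoters stranded `GRanges`
#' @param offset,width window placement in bp (defaults 500 and 250)
#' @return `GRanges` of upstream windows (metadata carried through)
#' @export
upstream_window <- function(promoters, offset = 500L, width = 250L) {
  st <- as.character(GenomicRanges::strand(promoters))
  s5 <- ifelse(st == "+", GenomicRanges::start(promoters),
               GenomicRanges::end(promoters))
  s <- ifelse(st == "+", s5 - offset, s5 + offset - width + 1L)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(promoters),
                                IRanges::IRanges(s, width = width), st)
  check_that(all(GenomicRanges::start(out) >= 1L),
             "upstream window extends past chromosome start")
  GenomeInfoDb::seqinfo(out) <- GenomeInfoDb::seqinfo(promoters)
  S4Vectors::mcols(out) <- S4Vectors::mcols(promoters)
  out
}

#' Read-through and expression gene filters
#'
#' Removes (a) genes whose wild-type signal in the upstream control window
#' exceeds `readthrough_max` RPKM (likely read-through from a highly
#' expressed upstream gene) and (b) genes whose promoter RPKM is below
#' `expressed_min` in every sample (non-expressed). The two rules are
#' applied independently, so their order does not matter; an audit log
#' records which rule removed each gene.
#'
#' @param upstream_rpkm_wt named numeric: wild-type upstream-window RPKM per
#'   gene
#' @param promoter_rpkm matrix (genes x samples) of promoter RPKM, rownames
#'   = gene ids matching `upstream_rpkm_wt`
#' @param readthrough_max RPKM threshold for rule (a), default 8
#' @param expressed_min RPKM threshold for rule (b), default 2
#' @return list with `kept` (character gene ids) and `removed` (data.frame:
#'   `gene_id`, `reason`)
#' @export
apply_expression_filters <- function(upstream_rpkm_wt, promoter_rpkm,
                                     readthrough_max = 8, expressed_min = 2) {
  genes <- rownames(promoter_rpkm)
  check_that(!is.null(genes), "promoter_rpkm needs gene rownames")
  check_that(identical(sort(genes), sort(names(upstream_rpkm_wt))),
             "gene sets of the two inputs differ")
  upstream_rpkm_wt <- upstream_rpkm_wt[genes]
  readthrough <- upstream_rpkm_wt > readthrough_max
  nonexpressed <- apply(promoter_rpkm < expressed_min, 1L, all)
  rt_ids <- genes[readthrough]
  ne_ids <- genes[nonexpressed & !readthrough]
  removed <- rbind(
    data.frame(gene_id = rt_ids, reason = rep("readthrough", length(rt_ids))),
    data.frame(gene_id = ne_ids,
               reason = rep("non_expressed", length(ne_ids))))
  list(kept = genes[!(readthrough | nonexpressed)],
       removed = removed)
}

#' Binned metagene signal profile
#'
#' Each region is oriented 5' to 3', split into `nbins` equal-size bins
#' (fractional base assignment, so regions shorter than `nbins` bp are
#' handled exactly rather than excluded), and averaged per bin. Optionally
#' each region's bin vector is min-max rescaled to \[0, 1\] before
#' averaging (used when comparing tracks of different dynamic range);
#' regions with `max == min` are skipped with a warning. Across regions each
#' bin is summarized by a two-sided trimmed mean (`trim` from each tail,
#' R's `mean(trim=)` convention), which discards extreme regions.
#'
#' @param track a `SignalTrack`
#' @param regions stranded `GRanges`
#' @param nbins number of bins (default 100)
#' @param trim trim fraction per tail in \[0, 0.5\] (default 0.3)
#' @param per_region_minmax rescale each region to \[0, 1\] first?
#' @return numeric vector of length `nbins`, with the per-region bin matrix
#'   in attribute `"matrix"`
#' @export
metaprofile <- function(track, regions, nbins = 100L, trim = 0.3,
                        per_region_minmax = FALSE) {
  check_that(length(regions) >= 1L, "no regions")
  check_that(trim >= 0 && trim <= 0.5, "trim must be in [0, 0.5]")
  rows <- vector("list", length(regions))
  skipped <- 0L
  for (i in seq_along(regions)) {
    v <- region_values(track, regions[i])
    b <- bin_means(v, nbins)
    if (per_region_minmax) {
      rng <- range(b)
      if (rng[2L] == rng[1L]) {
        skipped <- skipped + 1L
        next
      }
      b <- (b - rng[1L]) / (rng[2L] - rng[1L])
    }
    rows[[i]] <- b
  }
  if (skipped > 0L) {
    warning(sprintf("%d region(s) skipped (constant signal under min-max)",
                    skipped))
  }
  m <- do.call(rbind, rows)
  check_that(!is.null(m) && nrow(m) >= 1L, "all regions skipped")
  prof <- apply(m, 2L, mean, trim = trim)
  attr(prof, "matrix") <- m
  attr(prof, "trim") <- trim
  attr(prof, "minmax") <- per_region_minmax
  prof
}
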