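#' Build a PRO-seq 5'-end track from aligned read intervals
#'
#' Nascent-transcription signal is quantified by counting read 5' ends: each
#' read contributes a single unit at its strand-aware 5' coordinate (start on
#' `"+"`, end on `"-"`), on the track of its alignment strand. The track total
#' therefore equals the number of reads.
#'
#' @param reads a [GenomicRanges::GRanges] of read alignments with strand
#'   `"+"` or `"-"`
#' @param seqlengths named chromosome lengths; defaults to
#'   `seqlengths(reads)`, which must then be defined
#' @param flip_strand set to `TRUE` for library protocols in which the
#'   adaptor scheme inverts the sequenced strand relative to transcription
#' @return a stranded `SignalTrack` of 5'-end counts
#' @export
five_prime_track <- function(reads, seqlengths = NULL, flip_strand = FALSE) {
  if (is.null(seqlengths)) seqlengths <- GenomeInfoDb::seqlengths(reads)
  check_that(length(seqlengths) > 0 && !anyNA(seqlengths),
             "seqlengths must be supplied or set on 'reads'")
  st <- as.character(GenomicRanges::strand(reads))
  check_that(all(st %in% c("+", "-")), "all reads must be stranded")
  ch <- as.character(GenomicRanges::seqnames(reads))
  check_that(all(GenomicRanges::start(reads) >= 1L) &&
             all(GenomicRanges::end(reads) <= seqlengths[ch]),
             "read interval beyond chromosome bounds")
  if (flip_strand) st <- ifelse(st == "+", "-", "+")
  pos <- ifelse(st == "+", GenomicRanges::start(reads),
                GenomicRanges::end(reads))
  cov_for <- function(keep) {
    gr <- GenomicRanges::GRanges(ch[keep],
                                 IRanges::IRanges(pos[keep], width = 1L),
                                 seqlengths = seqlengths)
    GenomicRanges::coverage(gr)
  }
  SignalTrack(list("+" = cov_for(st == "+"), "-" = cov_for(st == "-")),
              units = "read 5' ends")
}

#' Spike-in size factors with geometric mean one
#'
#' Each sample's raw scaling factor is proportional to 1 / (spike-in reads),
#' so a sample in which more exogenous spike-in material was recovered is
#' scaled down. The factors are then rescaled to have geometric mean 1, the
#' convention used before differential analysis so the average library is
#' left untouched.
#'
#' @param target_totals reads mapped to the target (e.g. human) genome per
#'   sample; used only for validation, the factors depend on spike totals
#' @param spike_totals reads mapped to the spike-in (e.g. Drosophila) genome
#'   per sample; all must be positive
#' @return named numeric vector of size factors, geometric mean 1
#' @examples
#' compute_spikein_factors(c(1e6, 1e6), c(100, 200))  # (sqrt(2), 1/sqrt(2))
#' @export
compute_spikein_factors <- function(target_totals, spike_totals) {
  check_that(length(spike_totals) >= 1L, "no samples")
  check_that(missing(target_totals) || length(target_totals) == 0L ||
             length(target_totals) == length(spike_totals),
             "target and spike totals differ in length")
  if (!missing(target_totals) && length(target_totals))
    check_that(all(target_totals > 0), "non-positive target total")
  bad <- which(!(spike_totals > 0))
  if (length(bad)) {
    nm <- names(spike_totals)[bad]
    if (is.null(nm) || any(!nzchar(nm))) nm <- as.character(bad)
    stop(sprintf("zero/invalid spike-in count for sample(s): %s",
                 paste(nm, collapse = ", ")), call. = FALSE)
  }
  raw <- 1 / spike_totals
  f <- raw / geom_mean(raw)
  names(f) <- names(spike_totals)
  f
}

#' ChIP-seq spike-in scaling factor
#'
#' The ratio of uniquely mapped target-genome (human) reads to uniquely
#' mapped spike-in-genome (mouse) reads. Tracks are divided by this ratio
#' (see [chip_coverage_track()]), so samples with proportionally more
#' spike-in recovery end up with larger normalized signal, consistent with
#' the PRO-seq orientation.
#'
#' @param human_unique,mouse_unique unique read counts; `mouse_unique > 0`
#' @return the human/mouse ratio
#' @export
chip_scale_factor <- function(human_unique, mouse_unique) {
  check_that(is.numeric(human_unique) && is.numeric(mouse_unique),
             "counts must be numeric")
  check_that(all(mouse_unique > 0), "mouse (spike-in) unique count must be > 0")
  human_unique / mouse_unique
}

#' ChIP-seq coverage track from read 5' ends
#'
#' Each read is replaced by a 200 bp (by default) strand-aware extension
#' from its 5' end and per-base coverage is summed over both strands into a
#' single unstranded track. No clipping is applied at chromosome ends beyond
#' validity checks, so total coverage equals `ext * n_reads`.
#'
#' @param reads stranded [GenomicRanges::GRanges] of read alignments
#' @param seqlengths named chromosome lengths (default from `reads`)
#' @param ext extension length in bp (default 200)
#' @param scale_factor optional [chip_scale_factor()]; the coverage is
#'   divided by it
#' @return an unstranded `SignalTrack`
#' @export
chip_coverage_track <- function(reads, seqlengths = NULL, ext = 200L,
                                scale_factor = NULL) {
  if (is.null(seqlengths)) seqlengths <- GenomeInfoDb::seqlengths(reads)
  check_that(length(seqlengths) > 0 && !anyNA(seqlengths),
             "seqlengths must be supplied or set on 'reads'")
  st <- as.character(GenomicRanges::strand(reads))
  check_that(all(st %in% c("+", "-")), "all reads must be stranded")
  ch <- as.character(GenomicRanges::seqnames(reads))
  p5 <- ifelse(st == "+", GenomicRanges::start(reads),
               GenomicRanges::end(reads))
  s <- ifelse(st == "+", p5, p5 - ext + 1L)
  e <- s + ext - 1L
  check_that(all(s >= 1L) && all(e <= seqlengths[ch]),
             "extended read beyond chromosome bounds")
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, e),
                               seqlengths = seqlengths)
  cov <- GenomicRanges::coverage(gr)
  tr <- SignalTrack(list("*" = cov), units = "extended-read coverage")
  if (!is.null(scale_factor)) tr <- scale_track(tr, 1 / scale_factor)
  tr
}

#' Log2 ChIP/Input enrichment track
#'
#' Per base, `max(0, log2((chip + 1) / (input + 1)))`: pseudocounts of 1 on
#' both tracks and censoring of negative values to zero, so depleted regions
#' read as zero rather than negative enrichment.
#'
#' @param chip,input `SignalTrack`s on the same genome and strands
#' @return a `SignalTrack` of censored log2 enrichments
#' @export
log_enrichment_track <- function(chip, input) {
  check_that(identical(names(chip$signal), names(input$signal)),
             "chip and input tracks differ in strandedness")
  check_that(identical(chip$seqlengths, input$seqlengths),
             "chip and input tracks differ in chromosomes")
  out <- track_map(function(c, i) pmax(log2((c + 1) / (i + 1)), 0),
                   chip, input)
  out$units <- "log2 enrichment"
  out$scale_factor <- 1
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `count * 1e9 / (width * library_size)`, the expression unit used by the
#' read-through (`RPKM > 8`) and non-expressed (`RPKM < 2`) gene filters.
#' The library size is the raw number of mapped target-genome reads, not a
#' spike-normalized total, since RPKM is only used within-sample.
#'
#' @param count reads in the region (vectorized)
#' @param width_bp region length in bp, positive
#' @param library_size mapped reads in the library, positive
#' @return RPKM values
#' @export
region_rpkm <- function(count, width_bp, library_size) {
  check_that(all(width_bp > 0), "region length must be positive")
  check_that(all(library_size > 0), "library size must be positive")
  count * 1e9 / (width_bp * library_size)
}
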