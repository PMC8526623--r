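#' Promoter regions around TSS-region ends
#'
#' Extends each TSS region (e.g. a FANTOM5 CAGE cluster) into a promoter of
#' `2 * flank + 1` bp centred on an anchor point. The default anchor is the
#' strand-aware downstream boundary of the TSS region ("the putative end"):
#' the first base past the region's 3' edge. `anchor = "midpoint"` centres
#' on the region midpoint instead. Promoters are clipped at chromosome
#' bounds when `seqlengths` are available.
#'
#' @param tss [GenomicRanges::GRanges] of TSS regions, stranded, with a
#'   `gene_id` (or `name`) metadata column carried through
#' @param flank half-width in bp, must be positive (default 250)
#' @param anchor `"end"` (default) or `"midpoint"`
#' @return `GRanges` of promoters with the input metadata
#' @examples
#' tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1010), "+",
#'                               gene_id = "g1")
#' make_promoters(tss)  # 761..1261, width 501
#' @export
make_promoters <- function(tss, flank = 250L, anchor = c("end", "midpoint")) {
  anchor <- match.arg(anchor)
  check_that(is.numeric(flank) && length(flank) == 1L && flank > 0,
             "flank must be a single positive number")
  st <- as.character(GenomicRanges::strand(tss))
  check_that(all(st %in% c("+", "-")), "TSS regions must be stranded")
  a <- switch(anchor,
    end = ifelse(st == "+", GenomicRanges::end(tss) + 1L,
                 GenomicRanges::start(tss) - 1L),
    midpoint = floor((GenomicRanges::start(tss) + GenomicRanges::end(tss)) / 2))
  s <- a - flank
  e <- a + flank
  sl <- GenomeInfoDb::seqlengths(tss)
  ch <- as.character(GenomicRanges::seqnames(tss))
  if (length(sl) && !anyNA(sl)) {
    check_that(all(GenomicRanges::start(tss) >= 1L) &&
               all(GenomicRanges::end(tss) <= sl[ch]),
               "TSS region outside chromosome bounds")
    s <- pmax(s, 1L)
    e <- pmin(e, sl[ch])
  } else {
    check_that(all(s >= 1L), "promoter extends past chromosome start")
  }
  out <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, e), st)
  GenomeInfoDb::seqinfo(out) <- GenomeInfoDb::seqinfo(tss)
  S4Vectors::mcols(out) <- S4Vectors::mcols(tss)
  out
}

#' Assign promoters to their nearest same-strand transcript
#'
#' Each promoter is mapped to the nearest transcript on its own strand
#' (distance 0 when they overlap or are adjacent); promoters farther than
#' `max_dist` from any same-strand transcript are dropped and reported.
#'
#' @param promoters,transcripts stranded `GRanges`; `transcripts` must carry
#'   a `transcript_id` metadata column
#' @param max_dist maximum allowed gap in bp (default 2000)
#' @return a list with `assigned` (data.frame: `promoter`, `transcript_id`,
#'   `distance`) and `dropped` (integer indices of removed promoters)
#' @export
assign_to_transcript <- function(promoters, transcripts, max_dist = 2000L) {
  if (length(transcripts) == 0L) {
    warning("empty transcript set: all promoters dropped")
    return(list(assigned = data.frame(promoter = integer(0),
                                      transcript_id = character(0),
                                      distance = integer(0)),
                dropped = seq_along(promoters)))
  }
  pst <- as.character(GenomicRanges::strand(promoters))
  tst <- as.character(GenomicRanges::strand(transcripts))
  tid <- S4Vectors::mcols(transcripts)$transcript_id
  check_that(!is.null(tid), "transcripts need a transcript_id column")
  res <- data.frame(promoter = seq_along(promoters),
                    transcript_id = NA_character_,
                    distance = NA_integer_)
  for (s in c("+", "-")) {
    pi <- which(pst == s)
    ti <- which(tst == s)
    if (!length(pi) || !length(ti)) next
    hits <- GenomicRanges::distanceToNearest(promoters[pi], transcripts[ti],
                                             ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    res$transcript_id[pi[qh]] <- tid[ti[S4Vectors::subjectHits(hits)]]
    res$distance[pi[qh]] <- S4Vectors::mcols(hits)$distance
  }
  keep <- !is.na(res$distance) & res$distance <= max_dist
  list(assigned = res[keep, , drop = FALSE],
       dropped = which(!keep))
}

#' Representative gene body from a gene's transcript isoforms
#'
#' The representative transcript end is the modal strand-aware 3' end over
#' all annotated isoforms of the gene (exact coordinate equality); ties are
#' broken in favour of the end carried by the longest isoform. The gene body
#' runs from the promoter's strand-aware downstream boundary to that end.
#'
#' @param transcripts `GRanges` of one gene's isoforms (same strand/chrom)
#' @param promoter single-range `GRanges`, same strand
#' @return a single-range `GRanges` gene body; errors with class
#'   `"degenerate_gene"` if the representative end does not lie downstream
#'   of the promoter
#' @export
representative_gene_body <- function(transcripts, promoter) {
  check_that(length(transcripts) >= 1L, "need at least one transcript")
  check_that(length(promoter) == 1L, "need exactly one promoter")
  st <- unique(as.character(GenomicRanges::strand(transcripts)))
  ch <- unique(as.character(GenomicRanges::seqnames(transcripts)))
  check_that(length(st) == 1L && length(ch) == 1L,
             "transcripts must share one strand and chromosome")
  ends3 <- if (st == "+") GenomicRanges::end(transcripts) else
    GenomicRanges::start(transcripts)
  tab <- table(ends3)
  support <- as.integer(tab[as.character(ends3)])
  best <- max(support)
  cand <- which(support == best)
  if (length(unique(ends3[cand])) > 1L) {
    cand <- cand[which.max(GenomicRanges::width(transcripts)[cand])]
  }
  rep_end <- ends3[cand[1L]]
  if (st == "+") {
    s <- GenomicRanges::end(promoter) + 1L
    e <- rep_end
  } else {
    s <- rep_end
    e <- GenomicRanges::start(promoter) - 1L
  }
  if (s > e) {
    stop(structure(class = c("degenerate_gene", "error", "condition"),
                   list(message = "representative transcript end upstream of promoter end",
                        call = sys.call())))
  }
  GenomicRanges::GRanges(ch, IRanges::IRanges(s, e), st)
}

#' Pick the representative promoter of a gene by PRO-seq signal
#'
#' Among candidate promoters (a transcript overlapping several TSS regions),
#' returns the one with the highest mean signal over its interval; ties are
#' broken deterministically by the leftmost start.
#'
#' @param candidates `GRanges` of candidate promoters (>= 1)
#' @param track a `SignalTrack` (mean is taken on the promoter strand)
#' @return the selected single-range `GRanges`
#' @export
select_representative_promoter <- function(candidates, track) {
  check_that(length(candidates) >= 1L, "need at least one candidate")
  m <- region_signal(track, candidates, what = "mean")
  best <- which(m == max(m))
  if (length(best) > 1L) {
    best <- best[which.min(GenomicRanges::start(candidates)[best])]
  }
  candidates[best]
}
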