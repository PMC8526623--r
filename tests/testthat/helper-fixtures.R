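## Small in-code fixtures shared across test files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## stranded SignalTrack from plain per-base vectors (single chromosome)
track_from_vectors <- function(plus, minus = NULL, chrom = "chr1") {
  if (is.null(minus)) minus <- numeric(length(plus))
  stopifnot(length(plus) == length(minus))
  as_rlelist <- function(v) {
    x <- list(S4Vectors::Rle(v))
    names(x) <- chrom
    methods::as(x, "RleList")
  }
  SignalTrack(list("+" = as_rlelist(plus), "-" = as_rlelist(minus)))
}

## unstranded track from one vector
unstranded_track <- function(v, chrom = "chr1") {
  x <- list(S4Vectors::Rle(v))
  names(x) <- chrom
  SignalTrack(list("*" = methods::as(x, "RleList")))
}

## random stranded reads on one chromosome
random_reads <- function(n, chrom_len = 10000L, read_len = 50L,
                         chrom = "chr1") {
  s <- sample.int(chrom_len - read_len, n, replace = TRUE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, width = read_len),
          strand = sample(c("+", "-"), n, replace = TRUE),
          seqlengths = stats::setNames(chrom_len, chrom))
}

## brute-force tile filter/merge/length reference for the wave caller:
## quadratic scan over retained tiles, used as the oracle.
brute_force_regions <- function(tiles, params) {
  keep <- tiles$smoothed_covered >= params$min_covered_frac * params$tile &
    tiles$signal_sum >= params$min_tile_signal
  kt <- tiles[keep, , drop = FALSE]
  out <- list()
  for (ch in unique(kt$chrom)) {
    for (st in unique(kt$strand[kt$chrom == ch])) {
      d <- kt[kt$chrom == ch & kt$strand == st, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (!nrow(d)) next
      cur_s <- d$start[1L]; cur_e <- d$end[1L]
      for (i in seq_len(nrow(d))[-1L]) {
        gap <- d$start[i] - cur_e - 1L
        if (gap <= params$merge_gap) {
          cur_e <- max(cur_e, d$end[i])
        } else {
          out[[length(out) + 1L]] <- data.frame(chrom = ch, strand = st,
                                                start = cur_s, end = cur_e)
          cur_s <- d$start[i]; cur_e <- d$end[i]
        }
      }
      out[[length(out) + 1L]] <- data.frame(chrom = ch, strand = st,
                                            start = cur_s, end = cur_e)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[res$end - res$start + 1L >= params$min_region_len, , drop = FALSE]
  res <- res[order(res$chrom, res$strand, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## GRanges regions -> comparable data.frame
regions_to_df <- function(gr) {
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  strand = as.character(GenomicRanges::strand(gr)),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr))
  d <- d[order(d$chrom, d$strand, d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

## random tile table for oracle-equivalence tests
random_tiles <- function(n, params, chrom = "chr1", strand = "+") {
  covered <- sample(0:params$tile, n, replace = TRUE)
  ## mix of empty and strong tiles so both filters bite
  covered[runif(n) < 0.4] <- 0L
  sig <- round(runif(n, 0, 3), 2)
  sig[runif(n) < 0.3] <- 0
  sm <- pmax(c(covered[1L], covered[-n]), covered)
  starts <- seq.int(1L, by = params$tile, length.out = n)
  data.frame(chrom = chrom, strand = strand, start = starts,
             end = starts + params$tile - 1L, covered = covered,
             smoothed_covered = sm, signal_sum = sig)
}
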