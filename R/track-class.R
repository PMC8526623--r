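#' Strand-specific genomic signal tracks
#'
#' A `SignalTrack` holds per-base, non-negative signal as run-length encoded
#' vectors ([S4Vectors::Rle]), one [IRanges::RleList] per strand. PRO-seq
#' tracks carry read 5'-end counts on `"+"` and `"-"`; ChIP coverage tracks
#' are unstranded and use the single pseudo-strand `"*"`.
#'
#' @param signal named list of `RleList` (or coercible lists of `Rle`), with
#'   names `c("+", "-")` for a stranded track or `"*"` for an unstranded one.
#'   All elements must share chromosome names and lengths.
#' @param units free-text unit label carried as metadata
#' @param scale_factor scaling already applied to the values (bookkeeping)
#' @return an object of class `SignalTrack`
#' @examples
#' reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 101), width = 50),
#'                                 strand = c("+", "-"),
#'                                 seqlengths = c(chr1 = 1000))
#' tr <- five_prime_track(reads)
#' track_total(tr)
#' @export
SignalTrack <- function(signal, units = "reads", scale_factor = 1) {
  check_that(is.list(signal) && length(signal) >= 1L, "signal must be a list")
  nm <- names(signal)
  ok <- identical(sort(nm), sort(c("+", "-"))) || identical(nm, "*")
  check_that(ok, "signal must be named '+'/'-' (stranded) or '*' (unstranded)")
  signal <- lapply(signal, function(s) {
    if (!methods::is(s, "RleList")) s <- methods::as(s, "RleList")
    s
  })
  lens <- lapply(signal, lengths)
  for (i in seq_along(lens)[-1L]) {
    check_that(identical(lens[[1L]], lens[[i]]),
               "strands disagree on chromosome names/lengths")
  }
  structure(
    list(signal = signal,
         seqlengths = lens[[1L]],
         units = units,
         scale_factor = scale_factor),
    class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack (%s): %d chromosome(s), strands {%s}, total %.4g\n",
              x$units, length(x$seqlengths),
              paste(names(x$signal), collapse = ","), track_total(x)))
  invisible(x)
}

#' @rdname SignalTrack
#' @param x a `SignalTrack`
#' @export
is_stranded <- function(x) !identical(names(x$signal), "*")

#' Total signal of a track
#' @param x a `SignalTrack`
#' @return the sum of all per-base values over all strands
#' @export
track_total <- function(x) {
  sum(vapply(x$signal, function(s) sum(as.numeric(sum(s))), numeric(1)))
}

#' Scale every value of a track by a constant factor
#' @param x a `SignalTrack`
#' @param f positive finite multiplier
#' @return the scaled `SignalTrack`; `scale_factor` metadata accumulates `f`
#' @export
scale_track <- function(x, f) {
  check_that(is.numeric(f) && length(f) == 1L && is.finite(f) && f > 0,
             "scale factor must be a single positive number")
  x$signal <- lapply(x$signal, function(s) s * f)
  x$scale_factor <- x$scale_factor * f
  x
}

## apply a function per strand x chromosome over one or two tracks
track_map <- function(f, x, y = NULL) {
  sig <- lapply(names(x$signal), function(st) {
    sx <- x$signal[[st]]
    out <- lapply(names(sx), function(ch) {
      if (is.null(y)) f(sx[[ch]]) else f(sx[[ch]], y$signal[[st]][[ch]])
    })
    names(out) <- names(sx)
    methods::as(out, "RleList")
  })
  names(sig) <- names(x$signal)
  x$signal <- sig
  x
}

## strand label to use when querying `track` for a region strand `st`
.query_strand <- function(track, st) {
  if (!is_stranded(track)) return("*")
  if (st %in% c("+", "-")) st else "+"
}

#' Summarize track signal over regions
#'
#' Sums (or averages) the per-base signal of `track` over each region,
#' using the region's own strand for a stranded track (regions with strand
#' `"*"` on a stranded track read the `"+"` strand).
#'
#' @param track a `SignalTrack`
#' @param regions a [GenomicRanges::GRanges]
#' @param what `"sum"` or `"mean"`
#' @return numeric vector, one value per region
#' @export
region_signal <- function(track, regions, what = c("sum", "mean")) {
  what <- match.arg(what)
  n <- length(regions)
  out <- numeric(n)
  ch <- as.character(GenomicRanges::seqnames(regions))
  st <- as.character(GenomicRanges::strand(regions))
  for (i in seq_len(n)) {
    rle <- track$signal[[.query_strand(track, st[i])]][[ch[i]]]
    check_that(!is.null(rle), "chromosome '%s' not in track", ch[i])
    s <- GenomicRanges::start(regions)[i]
    e <- GenomicRanges::end(regions)[i]
    check_that(s >= 1L && e <= length(rle),
               "region %d outside chromosome '%s'", i, ch[i])
    out[i] <- sum(S4Vectors::window(rle, s, e))
  }
  if (what == "mean") out <- out / GenomicRanges::width(regions)
  out
}

## per-base values of one region, oriented 5'->3' (reversed on "-")
region_values <- function(track, region) {
  ch <- as.character(GenomicRanges::seqnames(region))
  st <- as.character(GenomicRanges::strand(region))
  rle <- track$signal[[.query_strand(track, st)]][[ch]]
  check_that(!is.null(rle), "chromosome '%s' not in track", ch)
  v <- as.numeric(S4Vectors::window(rle, GenomicRanges::start(region),
                                    GenomicRanges::end(region)))
  if (st == "-") rev(v) else v
}

#' Write / read stranded tracks as bedGraph pairs
#'
#' Stranded tracks use the conventional `<prefix>.plus.bedGraph` /
#' `<prefix>.minus.bedGraph` file pair; unstranded tracks a single
#' `<prefix>.bedGraph`. Coordinates on disk are 0-based half-open.
#'
#' @param track a `SignalTrack`
#' @param prefix path prefix (directories must exist)
#' @return `write_track_bedgraph` returns the written paths invisibly;
#'   `read_track_bedgraph` returns a `SignalTrack`.
#' @export
write_track_bedgraph <- function(track, prefix) {
  sl <- track$seqlengths
  paths <- character(0)
  for (st in names(track$signal)) {
    suff <- switch(st, "+" = ".plus.bedGraph", "-" = ".minus.bedGraph",
                   ".bedGraph")
    path <- paste0(prefix, suff)
    gr <- methods::as(track$signal[[st]], "GRanges")
    GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
    gr <- gr[S4Vectors::mcols(gr)$score != 0]
    rtracklayer::export(gr, path, format = "bedGraph")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_track_bedgraph
#' @param seqlengths named integer vector of chromosome lengths
#' @param stranded whether to read a `.plus/.minus` pair (else one file)
#' @param units,scale_factor metadata for the reconstructed track
#' @export
read_track_bedgraph <- function(prefix, seqlengths, stranded = TRUE,
                                units = "reads", scale_factor = 1) {
  read_one <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    score <- S4Vectors::mcols(gr)$score
    if (length(gr) == 0L || is.null(score)) {
      ## a track with no non-zero intervals exports as a bare header
      gr <- GenomicRanges::GRanges(seqlengths = seqlengths)
      score <- numeric(0)
    }
    gr <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr), GenomicRanges::ranges(gr),
      score = score, seqlengths = seqlengths)
    GenomicRanges::coverage(gr, weight = "score")
  }
  sig <- if (stranded) {
    list("+" = read_one(paste0(prefix, ".plus.bedGraph")),
         "-" = read_one(paste0(prefix, ".minus.bedGraph")))
  } else {
    list("*" = read_one(paste0(prefix, ".bedGraph")))
  }
  SignalTrack(sig, units = units, scale_factor = scale_factor)
}
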