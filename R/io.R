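#' Read a conversion-rate table from TSV
#'
#' Expects a header with columns `gene_id`, `condition`, `replicate`,
#' `timepoint_h`, `conversion_rate`. Malformed numeric fields are reported
#' with their line number (header = line 1).
#'
#' @param path TSV file path
#' @return data.frame suitable for [filter_conversion_genes()]
#' @export
read_conversion_table <- function(path) {
  check_that(file.exists(path), "no such file: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "condition", "replicate", "timepoint_h",
            "conversion_rate")
  check_that(all(need %in% names(tab)), "missing column(s): %s",
             paste(setdiff(need, names(tab)), collapse = ", "))
  for (col in c("replicate", "timepoint_h", "conversion_rate")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed value '%s' in column '%s' at line %d of %s",
                   tab[[col]][bad[1L]], col, bad[1L] + 1L, path),
           call. = FALSE)
    }
    tab[[col]] <- val
  }
  tab
}

#' Write a conversion-rate or generic table as TSV
#' @param x data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read TSS regions from BED6
#'
#' The BED name field becomes `gene_id`.
#'
#' @param path BED6 file
#' @param seqlengths optional named chromosome lengths to attach
#' @return stranded `GRanges` with `gene_id`
#' @export
read_tss_bed <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  S4Vectors::mcols(gr)$gene_id <- S4Vectors::mcols(gr)$name
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' Write a simulated data set to disk
#'
#' Writes the annotation (transcripts as BED6 and GTF, TSS regions as
#' BED6), each DRB-timecourse track as a `.plus/.minus` bedGraph pair, the
#' conversion table and the ground truth as TSV with headers.
#'
#' @param ann annotation from [make_toy_annotation()]
#' @param truth a [make_ground_truth()]
#' @param dir output directory (created if needed)
#' @param tracks optional output of [simulate_drb_timecourse()]
#' @param conversion optional output of [simulate_conversion_table()]
#' @return the written paths, invisibly
#' @export
write_simulation <- function(ann, truth, dir, tracks = NULL,
                             conversion = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tx <- ann$transcripts
  bed <- tx
  S4Vectors::mcols(bed) <- NULL
  S4Vectors::mcols(bed)$name <- S4Vectors::mcols(tx)$gene_id
  p <- file.path(dir, "transcripts.bed")
  rtracklayer::export(bed, p, format = "BED")
  paths <- c(paths, p)
  gtf <- tx
  S4Vectors::mcols(gtf)$type <- "transcript"
  S4Vectors::mcols(gtf)$source <- "polkinetics"
  p <- file.path(dir, "transcripts.gtf")
  rtracklayer::export(gtf, p, format = "gtf")
  paths <- c(paths, p)
  tssbed <- ann$tss
  S4Vectors::mcols(tssbed) <- NULL
  S4Vectors::mcols(tssbed)$name <- S4Vectors::mcols(ann$tss)$gene_id
  p <- file.path(dir, "tss.bed")
  rtracklayer::export(tssbed, p, format = "BED")
  paths <- c(paths, p)
  p <- file.path(dir, "ground_truth.tsv")
  write_tsv_table(truth$genes, p)
  paths <- c(paths, p)
  p <- file.path(dir, "size_factors.tsv")
  write_tsv_table(data.frame(sample = seq_along(truth$size_factors),
                             size_factor = truth$size_factors), p)
  paths <- c(paths, p)
  if (!is.null(tracks)) {
    for (tp in names(tracks)) {
      paths <- c(paths, write_track_bedgraph(
        tracks[[tp]], file.path(dir, sprintf("proseq_t%s", tp))))
    }
  }
  if (!is.null(conversion)) {
    p <- file.path(dir, "conversion_rates.tsv")
    write_tsv_table(conversion, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
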