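#' End-to-end DRB-washout elongation-rate pipeline
#'
#' For each condition, subtracts the t = 0 track from every later washout
#' timepoint, tiles and filters the censored difference tracks, calls
#' contiguously expressed regions, annotates them to the closest upstream
#' TSS, and derives per-gene elongation rates (genes must carry a region at
#' every condition and timepoint). A manifest records the parameters, input
#' checksums and gene counts surviving each stage, so reruns on identical
#' inputs are byte-comparable.
#'
#' @param tracks nested named list: `tracks[[condition]][[timepoint]]` is a
#'   stranded `SignalTrack`; every condition needs a `"0"` entry and at
#'   least one later timepoint, and all conditions must share timepoints
#' @param tss stranded `GRanges` with `gene_id`
#' @param params a [wave_params()]
#' @param gene_subset optional gene ids for the median summary (e.g. genes
#'   longer than 100 kb)
#' @return list: `rates`, `excluded`, `regions` (`GRanges`), `medians`,
#'   `manifest`
#' @export
run_drb_pipeline <- function(tracks, tss, params = wave_params(),
                             gene_subset = NULL) {
  check_that(is.list(tracks) && length(tracks) >= 1L &&
             !is.null(names(tracks)), "tracks must be a named list by condition")
  tp_sets <- lapply(tracks, names)
  for (cond in names(tracks)) {
    tp <- tp_sets[[cond]]
    check_that("0" %in% tp,
               "condition '%s' is missing the t = 0 track", cond)
    check_that(length(setdiff(tp, "0")) >= 1L,
               "condition '%s' has no post-washout timepoint", cond)
    check_that(identical(sort(tp), sort(tp_sets[[1L]])),
               "conditions disagree on timepoints: '%s'", cond)
  }
  all_regions <- list()
  n_tiles_kept <- list()
  for (cond in names(tracks)) {
    t0 <- tracks[[cond]][["0"]]
    for (tp in setdiff(names(tracks[[cond]]), "0")) {
      d <- difference_track(tracks[[cond]][[tp]], t0)
      tiles <- tile_and_smooth(d, params)
      reg <- call_expressed_regions(tiles, params)
      reg <- annotate_to_upstream_tss(reg, tss)
      if (length(reg)) {
        S4Vectors::mcols(reg)$condition <- cond
        S4Vectors::mcols(reg)$timepoint <- as.numeric(tp)
      }
      all_regions[[paste(cond, tp, sep = ":")]] <- reg
      n_tiles_kept[[paste(cond, tp, sep = ":")]] <- length(reg)
    }
  }
  regions <- do.call(c, unname(all_regions))
  res <- elongation_rates(regions)
  med <- median_rates(res$rates, genes = gene_subset)
  manifest <- list(
    params = unclass(params),
    input_checksums = vapply(
      unlist(tracks, recursive = FALSE),
      function(tr) obj_checksum(tr$signal), character(1)),
    tss_checksum = obj_checksum(tss),
    n_regions = unlist(n_tiles_kept),
    n_genes_rated = length(unique(res$rates$gene_id)),
    n_genes_excluded = length(unique(res$excluded$gene_id)))
  list(rates = res$rates, excluded = res$excluded, regions = regions,
       medians = med, manifest = manifest)
}

#' End-to-end decay (half-life) pipeline
#'
#' Applies the detectability/monotonicity filters to a conversion table and
#' fits per-gene, per-condition half-lives with the robust decay model;
#' summary medians are reported over the shared gene set defined in all
#' conditions. The manifest records parameters, the input checksum and gene
#' counts surviving the filter.
#'
#' @param conversion conversion-rate data.frame or a TSV path readable by
#'   [read_conversion_table()]
#' @param min_detected_reps detectability threshold (default 3 replicates)
#' @param pool_replicates see [half_life_table()]
#' @return list: `half_lives`, `summary`, `removed`, `manifest`
#' @export
run_slam_pipeline <- function(conversion, min_detected_reps = 3L,
                              pool_replicates = TRUE) {
  if (is.character(conversion)) {
    conversion <- read_conversion_table(conversion)
  }
  filt <- filter_conversion_genes(conversion, min_detected_reps)
  hl <- half_life_table(filt$table, pool_replicates = pool_replicates)
  manifest <- list(
    params = list(min_detected_reps = min_detected_reps,
                  pool_replicates = pool_replicates),
    input_checksum = obj_checksum(conversion),
    n_genes_in = length(unique(conversion$gene_id)),
    n_genes_kept = length(unique(filt$table$gene_id)),
    n_genes_removed = nrow(filt$removed))
  list(half_lives = hl$half_lives, summary = hl$summary,
       removed = filt$removed, manifest = manifest)
}
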