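test_that("difference tracks subtract t0 and censor negatives", {
  a <- track_from_vectors(c(5, 1, 2, 0))
  b <- track_from_vectors(c(2, 2, 2, 0))
  d <- difference_track(a, b)
  expect_equal(as.numeric(d$signal[["+"]][["chr1"]]), c(3, 0, 0, 0))

  ## difference with itself is identically zero
  dd <- difference_track(a, a)
  expect_equal(track_total(dd), 0)

  ## censored differences are non-negative for any random pair
  set.seed(31)
  for (i in 1:10) {
    x <- track_from_vectors(rpois(200, 1), rpois(200, 1))
    y <- track_from_vectors(rpois(200, 1), rpois(200, 1))
    d <- difference_track(x, y)
    expect_true(all(as.numeric(d$signal[["+"]][["chr1"]]) >= 0))
    expect_true(all(as.numeric(d$signal[["-"]][["chr1"]]) >= 0))
  }
})

test_that("tile_and_smooth counts covered bases and smooths with max()", {
  ## 3 tiles of 1000: covered (300, 0, 300) -> smoothed (300, 300, 300)
  v <- numeric(3000)
  v[1:300] <- 1
  v[2301:2600] <- 2
  tiles <- tile_and_smooth(track_from_vectors(v), wave_params())
  plus <- tiles[tiles$strand == "+", ]
  expect_equal(plus$covered, c(300, 0, 300))
  expect_equal(plus$smoothed_covered, c(300, 300, 300))
  expect_equal(plus$signal_sum, c(300, 0, 600))

  ## all-zero track -> all-zero tiles
  z <- tile_and_smooth(track_from_vectors(numeric(2500)), wave_params())
  expect_true(all(z$covered == 0) && all(z$signal_sum == 0))
  ## last partial tile kept and clipped
  expect_equal(max(z$end[z$strand == "+"]), 2500)
  expect_equal(z$end - z$start + 1, rep(c(1000, 1000, 500), 2))
})

test_that("the max-smoothing rule matches an explicit loop on random vectors", {
  set.seed(41)
  p <- wave_params(tile = 100L)
  for (trial in 1:50) {
    n <- sample(2:30, 1)
    v <- numeric(n * 100)
    covered_truth <- integer(n)
    for (i in seq_len(n)) {
      k <- sample(0:100, 1)
      if (k > 0) {
        idx <- (i - 1) * 100 + sample.int(100, k)
        v[idx] <- rpois(k, 2) + 1
      }
      covered_truth[i] <- k
    }
    tiles <- tile_and_smooth(track_from_vectors(v), p)
    plus <- tiles[tiles$strand == "+", ]
    ## non-iterative reference: loop over tiles, max of raw current/previous
    sm <- numeric(n)
    for (i in seq_len(n)) {
      sm[i] <- if (i == 1) covered_truth[1] else
        max(covered_truth[i - 1], covered_truth[i])
    }
    expect_equal(plus$covered, covered_truth)
    expect_equal(plus$smoothed_covered, sm)
  }
})

test_that("region calling keeps >= 3 kb and merges gaps <= 4 kb", {
  p <- wave_params()
  mk_tiles <- function(covered, sig = rep(1, length(covered))) {
    n <- length(covered)
    starts <- seq.int(1L, by = 1000L, length.out = n)
    data.frame(chrom = "chr1", strand = "+", start = starts,
               end = starts + 999L, covered = covered,
               smoothed_covered = pmax(c(covered[1], covered[-n]), covered),
               signal_sum = sig)
  }
  ## three retained tiles -> one region of exactly 3000 bp, kept (boundary)
  reg <- call_expressed_regions(mk_tiles(c(900, 900, 900)), p)
  expect_equal(width(reg), 3000)

  ## two retained tiles separated by 5 kb of dropped tiles -> both regions
  ## are 1 kb (after failing to merge) and are filtered out
  reg2 <- call_expressed_regions(mk_tiles(c(900, 0, 0, 0, 0, 0, 900),
                                          c(1, 0, 0, 0, 0, 0, 1)), p)
  ## smoothing rescues the tile after each retained tile only if its signal
  ## passes; here intervening sums are 0 so regions stay short
  expect_equal(length(reg2), 0)

  ## a 4 kb gap is merged, a 5 kb gap is not (given long flanks)
  covered <- c(rep(900, 4), rep(0, 4), rep(900, 4))
  sig <- c(rep(1, 4), rep(0, 4), rep(1, 4))
  reg3 <- call_expressed_regions(mk_tiles(covered, sig), p)
  expect_equal(length(reg3), 1)   # gap 0-covered tiles: 5th tile smoothed in
  ## make the gap a true 5 kb by padding: tiles 5..9 all dropped
  covered2 <- c(rep(900, 4), rep(0, 5), rep(900, 4))
  sig2 <- c(rep(1, 4), rep(0, 5), rep(1, 4))
  reg4 <- call_expressed_regions(mk_tiles(covered2, sig2), p)
  expect_equal(length(reg4), 2)
})

test_that("filter/merge/length pipeline equals the brute-force oracle", {
  set.seed(53)
  p <- wave_params()
  for (trial in 1:1000) {
    tiles <- random_tiles(sample(5:60, 1), p)
    got <- regions_to_df(call_expressed_regions(tiles, p))
    want <- brute_force_regions(tiles, p)
    expect_identical(got, want)
  }
})

test_that("regions annotate to the closest upstream TSS", {
  tss <- GRanges("chr1", IRanges(c(8000, 50000), width = 10), "+",
                 gene_id = c("gA", "gB"))
  reg <- GRanges("chr1", IRanges(10001, 20000), "+")
  ann <- annotate_to_upstream_tss(reg, tss)
  expect_equal(mcols(ann)$gene_id, "gA")
  expect_equal(mcols(ann)$tss_pos, 8000)

  ## region upstream of all TSS -> unassigned, dropped
  reg2 <- GRanges("chr1", IRanges(1000, 5000), "+")
  expect_equal(length(annotate_to_upstream_tss(reg2, tss)), 0)

  ## a TSS inside the region is eligible (tile-quantized region starts
  ## slightly upstream of the TSS that launched it)
  reg3 <- GRanges("chr1", IRanges(49001, 60000), "+")
  expect_equal(mcols(annotate_to_upstream_tss(reg3, tss))$gene_id, "gB")

  ## minus strand mirror: upstream = larger coordinates
  tssm <- GRanges("chr1", IRanges(c(30000, 90000), width = 10), "-",
                  gene_id = c("gC", "gD"))
  regm <- GRanges("chr1", IRanges(15000, 25000), "-")
  expect_equal(mcols(annotate_to_upstream_tss(regm, tssm))$gene_id, "gC")
})

test_that("upstream-TSS annotation matches a brute-force scan", {
  set.seed(61)
  for (trial in 1:50) {
    n_tss <- sample(3:15, 1)
    tss <- GRanges("chr1",
                   IRanges(sample.int(200000L, n_tss), width = 10),
                   strand = sample(c("+", "-"), n_tss, replace = TRUE),
                   gene_id = sprintf("g%02d", seq_len(n_tss)))
    n_reg <- 10
    rs <- sample.int(180000L, n_reg)
    reg <- GRanges("chr1", IRanges(rs, rs + sample(3000:20000, n_reg, TRUE)),
                   strand = sample(c("+", "-"), n_reg, replace = TRUE))
    ann <- annotate_to_upstream_tss(reg, tss)
    tpos <- ifelse(as.character(strand(tss)) == "+", start(tss), end(tss))
    for (i in seq_along(reg)) {
      st <- as.character(strand(reg[i]))
      same <- which(as.character(strand(tss)) == st)
      cand <- if (st == "+") same[tpos[same] <= end(reg)[i]] else
        same[tpos[same] >= start(reg)[i]]
      hit <- which(start(ann) == start(reg)[i] & end(ann) == end(reg)[i] &
                     as.character(strand(ann)) == st)
      if (!length(cand)) {
        expect_equal(length(hit), 0)
      } else {
        best <- if (st == "+") cand[which.max(tpos[cand])] else
          cand[which.min(tpos[cand])]
        expect_true(mcols(tss)$gene_id[best] %in% mcols(ann)$gene_id[hit])
      }
    }
  }
})

test_that("elongation rates are edge distance over washout time", {
  tss <- GRanges("chr1", IRanges(c(1000, 200000), width = 10), "+",
                 gene_id = c("g1", "g2"))
  mk_reg <- function(s, e, cond, tp, gid, tpos) {
    g <- GRanges("chr1", IRanges(s, e), "+")
    mcols(g)$gene_id <- gid; mcols(g)$tss_pos <- tpos
    mcols(g)$condition <- cond; mcols(g)$timepoint <- tp
    g
  }
  regs <- c(
    mk_reg(1000, 34700, "WT", 10, "g1", 1000),   # 33,700 bp -> 3.37 kb/min
    mk_reg(1000, 60000, "WT", 25, "g1", 1000),
    mk_reg(200000, 226200, "WT", 10, "g2", 200000),  # 26,200 -> 2.62
    mk_reg(200000, 250000, "WT", 25, "g2", 200000))
  res <- elongation_rates(regs)
  r <- res$rates
  expect_equal(r$rate[r$gene_id == "g1" & r$timepoint == 10], 3.37)
  expect_equal(r$rate[r$gene_id == "g2" & r$timepoint == 10], 2.62)

  ## a gene missing one (condition, timepoint) is excluded everywhere
  res2 <- elongation_rates(regs[-2])
  expect_false("g1" %in% res2$rates$gene_id)
  expect_true("g1" %in% res2$excluded$gene_id)
  expect_true("g2" %in% res2$rates$gene_id)

  ## t = 0 regions are rejected
  bad <- mk_reg(1000, 2000, "WT", 0, "g1", 1000)
  expect_error(elongation_rates(c(regs, bad)), "positive")
})

test_that("processivity index is log10 distal/proximal", {
  ## constructed track: 100 reads in the first 10%, 1000 in the last 10%
  v <- numeric(10000)
  v[1:1000] <- 0.1       # proximal sum 100
  v[9001:10000] <- 1     # distal sum 1000
  gb <- GRanges("chr1", IRanges(1, 10000), "+")
  pi1 <- processivity_index(track_from_vectors(v), gb)
  expect_equal(pi1$index, 1)

  ## equal windows -> 0
  v2 <- rep(1, 10000)
  expect_equal(processivity_index(track_from_vectors(v2), gb)$index, 0)

  ## uniform Poisson track: index ~ 0 within 3 SE of the count ratio
  set.seed(71)
  lam <- 0.5
  v3 <- rpois(100000, lam)
  gb3 <- GRanges("chr1", IRanges(1, 100000), "+")
  res <- processivity_index(track_from_vectors(v3), gb3)
  n <- res$proximal + res$distal
  se_log10 <- sqrt(1 / res$proximal + 1 / res$distal) / log(10)
  expect_lt(abs(res$index), 3 * se_log10)

  ## zero proximal reads -> NA with flag
  v4 <- numeric(10000); v4[9001:10000] <- 1
  res4 <- processivity_index(track_from_vectors(v4), gb)
  expect_true(is.na(res4$index))
  expect_equal(res4$flag, "zero_proximal")
})
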