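#' Detectability and monotonicity filters for conversion-rate tables
#'
#' Keeps genes that satisfy, in every condition: (i) conversion rate > 0 in
#' at least `min_detected_reps` replicates at every timepoint, (ii) median
#' conversion at the 0 h timepoint > 0, and (iii) median conversion rates
#' non-increasing across ordered chase timepoints. Genes failing any rule
#' are removed with the reason logged.
#'
#' @param table data.frame with columns `gene_id`, `condition`, `replicate`,
#'   `timepoint_h`, `conversion_rate`
#' @param min_detected_reps minimum replicates with rate > 0 (default 3)
#' @return list with `table` (kept rows) and `removed` (data.frame:
#'   `gene_id`, `reason`)
#' @export
filter_conversion_genes <- function(table, min_detected_reps = 3L) {
  need <- c("gene_id", "condition", "replicate", "timepoint_h",
            "conversion_rate")
  check_that(all(need %in% names(table)), "missing column(s): %s",
             paste(setdiff(need, names(table)), collapse = ", "))
  check_that(all(table$conversion_rate >= 0 & table$conversion_rate <= 1),
             "conversion rates must lie in [0, 1]")
  check_that(0 %in% table$timepoint_h, "table must include the 0 h timepoint")
  reasons <- character(0)
  genes <- unique(table$gene_id)
  removed <- lapply(genes, function(g) {
    d <- table[table$gene_id == g, , drop = FALSE]
    for (cond in unique(d$condition)) {
      dc <- d[d$condition == cond, , drop = FALSE]
      tps <- sort(unique(dc$timepoint_h))
      det <- vapply(tps, function(t) {
        sum(dc$conversion_rate[dc$timepoint_h == t] > 0)
      }, numeric(1))
      if (any(det < min_detected_reps)) {
        return(data.frame(gene_id = g, reason = "undetected"))
      }
      med <- vapply(tps, function(t) {
        stats::median(dc$conversion_rate[dc$timepoint_h == t])
      }, numeric(1))
      if (med[tps == 0] <= 0) {
        return(data.frame(gene_id = g, reason = "zero_at_t0"))
      }
      if (any(diff(med) > 0)) {
        return(data.frame(gene_id = g, reason = "non_monotonic"))
      }
    }
    NULL
  })
  removed <- do.call(rbind, removed)
  if (is.null(removed)) {
    removed <- data.frame(gene_id = character(0), reason = character(0))
  }
  list(table = table[!(table$gene_id %in% removed$gene_id), , drop = FALSE],
       removed = removed)
}

#' Robust exponential-decay fit on linearized data
#'
#' Fits `ln(r) = a - k * t` by iteratively reweighted least squares with
#' Huber weights (tuning constant 1.345, scale = median absolute residual /
#' 0.6745, convergence tolerance 1e-8, at most 50 iterations), the
#' documented behaviour of the classic robust linear model. The half-life
#' is `ln(2) / k` for `k > 0` and undefined (`NA`, flagged) otherwise.
#'
#' @param t_h timepoints (hours); at least two distinct values over >= 3
#'   points
#' @param conversion conversion rates, all > 0
#' @param huber_c,tol,maxit IRLS tuning parameters
#' @return list: `k` (per hour), `intercept` (log-rate), `half_life`
#'   (hours, `NA` if `k <= 0`), `n_points`, `converged`, `weights`
#' @examples
#' fit_decay_robust(c(0, 6, 12), c(0.02, 0.01, 0.005))$half_life  # 6 h
#' @export
fit_decay_robust <- function(t_h, conversion, huber_c = 1.345, tol = 1e-8,
                             maxit = 50L) {
  check_that(length(t_h) == length(conversion), "input lengths differ")
  check_that(length(t_h) >= 3L, "need at least 3 points")
  check_that(length(unique(t_h)) >= 2L,
             "degenerate design: single distinct timepoint")
  check_that(all(conversion > 0), "non-positive conversion rate")
  y <- log(conversion)
  X <- cbind(1, t_h)
  qx <- qr(X)
  beta <- qr.coef(qx, y)              # OLS start
  converged <- FALSE
  w <- rep(1, length(y))
  for (it in seq_len(maxit)) {
    res <- y - drop(X %*% beta)
    s <- stats::median(abs(res)) / 0.6745
    if (s < .Machine$double.eps^0.5 * max(1, stats::mad(y, constant = 1))) {
      ## residuals (essentially) zero: perfect fit, unit weights
      w <- rep(1, length(y))
      converged <- TRUE
      break
    }
    w <- pmin(1, huber_c * s / abs(res))
    w[abs(res) == 0] <- 1
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(X * sw), y * sw)
    if (max(abs(beta_new - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  k <- -unname(beta[2L])
  list(k = k,
       intercept = unname(beta[1L]),
       half_life = if (k > 0) log(2) / k else NA_real_,
       n_points = length(y),
       converged = converged,
       weights = w)
}

#' Half-life table per gene and condition
#'
#' Runs [fit_decay_robust()] for every (gene, condition), pooling all
#' replicate points into one fit (the robust loss downweights outlier
#' replicates); `pool_replicates = FALSE` instead fits each replicate
#' separately and reports the median of the per-replicate decay constants.
#' Rows with non-positive conversion rates are excluded from the fit (the
#' filters should make this rare). The per-condition summary medians are
#' computed over genes with a defined half-life in all conditions, so every
#' condition is summarized on one shared gene set.
#'
#' @param table filtered conversion table (see [filter_conversion_genes()])
#' @param pool_replicates pool replicates into one fit? (default TRUE)
#' @return list with `half_lives` (data.frame: `gene_id`, `condition`, `k`,
#'   `intercept`, `half_life`, `n_points`, `converged`) and `summary`
#'   (data.frame: `condition`, `n_genes`, `median_half_life`)
#' @export
half_life_table <- function(table, pool_replicates = TRUE) {
  table <- table[table$conversion_rate > 0, , drop = FALSE]
  sp <- split(table, list(table$gene_id, table$condition), drop = TRUE)
  rows <- lapply(sp, function(d) {
    fit <- if (pool_replicates) {
      tryCatch(fit_decay_robust(d$timepoint_h, d$conversion_rate),
               error = function(e) NULL)
    } else {
      ks <- lapply(split(d, d$replicate), function(dr) {
        tryCatch(fit_decay_robust(dr$timepoint_h, dr$conversion_rate),
                 error = function(e) NULL)
      })
      ks <- ks[!vapply(ks, is.null, logical(1))]
      if (!length(ks)) NULL else {
        k <- stats::median(vapply(ks, `[[`, numeric(1), "k"))
        list(k = k,
             intercept = stats::median(vapply(ks, `[[`, numeric(1),
                                              "intercept")),
             half_life = if (k > 0) log(2) / k else NA_real_,
             n_points = nrow(d),
             converged = all(vapply(ks, `[[`, logical(1), "converged")))
      }
    }
    if (is.null(fit)) {
      return(data.frame(gene_id = d$gene_id[1L], condition = d$condition[1L],
                        k = NA_real_, intercept = NA_real_,
                        half_life = NA_real_, n_points = nrow(d),
                        converged = FALSE))
    }
    data.frame(gene_id = d$gene_id[1L], condition = d$condition[1L],
               k = fit$k, intercept = fit$intercept,
               half_life = fit$half_life, n_points = fit$n_points,
               converged = fit$converged)
  })
  hl <- do.call(rbind, rows)
  rownames(hl) <- NULL
  conds <- unique(hl$condition)
  ok <- hl[!is.na(hl$half_life), , drop = FALSE]
  shared <- names(which(table(ok$gene_id) == length(conds)))
  ok <- ok[ok$gene_id %in% shared, , drop = FALSE]
  summary <- do.call(rbind, lapply(split(ok, ok$condition), function(d) {
    data.frame(condition = d$condition[1L], n_genes = nrow(d),
               median_half_life = stats::median(d$half_life))
  }))
  rownames(summary) <- NULL
  list(half_lives = hl, summary = summary)
}

#' Transcript-buffering statistic
#'
#' Per gene, the difference between the steady-state (RNA-seq) and nascent
#' (PRO-seq) log2 fold changes, `delta = l2fc_rna - l2fc_pro`. Under pure
#' transcriptional change the two fold changes cancel; a distribution of
#' deltas skewed above zero indicates that steady-state mRNA changes exceed
#' production changes, i.e. altered mRNA stability.
#'
#' @param l2fc_rna,l2fc_pro named numeric vectors of per-gene log2 fold
#'   changes; genes missing in either input are dropped (counted)
#' @return list with `scores` (data.frame: `gene_id`, `delta`) and
#'   `summary` (`n`, `n_dropped`, `median`, `frac_positive`)
#' @export
buffering_statistic <- function(l2fc_rna, l2fc_pro) {
  check_that(!is.null(names(l2fc_rna)) && !is.null(names(l2fc_pro)),
             "inputs must be named by gene")
  common <- intersect(names(l2fc_rna), names(l2fc_pro))
  dropped <- length(union(names(l2fc_rna), names(l2fc_pro))) - length(common)
  delta <- l2fc_rna[common] - l2fc_pro[common]
  keep <- is.finite(delta)
  dropped <- dropped + sum(!keep)
  delta <- delta[keep]
  list(scores = data.frame(gene_id = names(delta), delta = unname(delta)),
       summary = list(n = length(delta), n_dropped = dropped,
                      median = stats::median(delta),
                      frac_positive = mean(delta > 0)))
}

#' Simple normalized log2 fold changes between two conditions
#'
#' Counts are scaled per sample by spike-in size factors, averaged within
#' condition, and compared with a pseudocount of 1:
#' `log2((mean_norm_cond + 1) / (mean_norm_ref + 1))`. This is the light
#' normalized contrast used for the buffering statistic; shrinkage-based
#' differential testing is out of scope.
#'
#' @param counts matrix (genes x samples) with gene rownames
#' @param size_factors per-sample factors (counts are multiplied by them)
#' @param groups character vector of condition labels per sample
#' @param cond,ref condition labels to contrast
#' @return named numeric vector of log2 fold changes
#' @export
normalized_l2fc <- function(counts, size_factors, groups, cond, ref) {
  check_that(ncol(counts) == length(size_factors) &&
             ncol(counts) == length(groups), "dimension mismatch")
  check_that(all(c(cond, ref) %in% groups), "unknown condition label")
  norm <- sweep(counts, 2L, size_factors, `*`)
  m1 <- rowMeans(norm[, groups == cond, drop = FALSE])
  m0 <- rowMeans(norm[, groups == ref, drop = FALSE])
  stats::setNames(log2((m1 + 1) / (m0 + 1)), rownames(counts))
}
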