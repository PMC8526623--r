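#' Geometric mean
#'
#' @param x positive numeric vector
#' @return the geometric mean of `x`
#' @keywords internal
geom_mean <- function(x) {
  stopifnot(is.numeric(x), all(x > 0))
  exp(mean(log(x)))
}

## assert helper with a formatted message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

#' Checksum of an arbitrary R object
#'
#' Serializes the object to a temporary file and returns its md5 digest.
#' Used by the pipeline manifests so reruns can be compared byte-wise.
#'
#' @param x any R object
#' @return a character md5 string
#' @export
obj_checksum <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  ## version = 2 keeps the serialization stable across minor R versions
  con <- file(tf, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(tf))
}

## mean of x over equal-size bins with fractional base assignment.
## Bin j covers [L(j-1)/nbins, Lj/nbins) in 0-based base units; a base
## straddling an edge contributes proportionally to both bins, so the result
## is exact for any L, including L < nbins.
bin_means <- function(x, nbins) {
  L <- length(x)
  stopifnot(L >= 1L, nbins >= 1L)
  if (L %% nbins == 0L) {
    return(colMeans(matrix(x, nrow = L %/% nbins)))
  }
  cs <- c(0, cumsum(x))
  S <- function(p) {           # integral of the step function on [0, p]
    i <- floor(p)
    v <- cs[i + 1L]
    frac <- p - i
    add <- ifelse(frac > 0 & i < L, frac * x[pmin(i + 1L, L)], 0)
    v + add
  }
  edges <- L * (0:nbins) / nbins
  (S(edges[-1L]) - S(edges[-(nbins + 1L)])) / (L / nbins)
}
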