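#' GC-correct a binned read-count matrix
#'
#' Per cell, counts are rescaled by the ratio of the cell's global median
#' count to the median count of the bin's GC-decile stratum, removing smooth
#' multiplicative GC bias while preserving total per-cell signal up to the
#' stratum correction. Blacklisted bins are dropped from the output. Strata
#' with fewer than 10 bins (and bins with missing GC) fall back to the global
#' median, i.e. no correction.
#'
#' @param counts a [read_count_matrix()].
#' @param binmap bin map (defaults to the one bound to `counts`).
#' @return A list of class `"corrected_counts"`: `binmap` (blacklisted bins
#'   removed) and `counts` (real-valued corrected matrix).
#' @export
gc_correct <- function(counts, binmap = counts$binmap) {
  stopifnot(inherits(counts, "read_counts"))
  assert_that(same_binmap(counts$binmap, binmap),
              "counts are bound to a different bin map")
  keep <- !binmap$blacklisted
  assert_that(any(keep), "all bins are blacklisted")
  bm <- binmap[keep, , drop = FALSE]
  class(bm) <- class(binmap)
  attr(bm, "avg_width") <- attr(binmap, "avg_width")
  attr(bm, "step") <- attr(binmap, "step")
  mat <- counts$counts[keep, , drop = FALSE]

  gc <- bm$gc
  stratum <- rep(NA_integer_, nrow(bm))
  ok <- !is.na(gc)
  if (any(ok)) {
    qs <- unique(stats::quantile(gc[ok], probs = seq(0, 1, 0.1), type = 7))
    if (length(qs) >= 2)  # constant GC collapses to a single uncorrected stratum
      stratum[ok] <- as.integer(cut(gc[ok], breaks = qs, include.lowest = TRUE))
  }
  corrected <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    gmed <- median(x)
    for (s in unique(stratum[!is.na(stratum)])) {
      sel <- which(!is.na(stratum) & stratum == s)
      if (length(sel) < 10) next
      smed <- median(x[sel])
      if (smed > 0 && gmed > 0) corrected[sel, j] <- x[sel] * gmed / smed
    }
  }
  structure(list(binmap = bm, counts = corrected), class = "corrected_counts")
}
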