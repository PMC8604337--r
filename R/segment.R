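#' Copy-number caller parameters
#'
#' Defaults follow the curation rules used throughout the package: 90%
#' concordance between the two segmentation algorithms and at least 5 reads
#' per bin per chromosome copy for a library to be retained (a cell at
#' exactly 5.0 passes; "less than 5" is discarded).
#'
#' @param concordance_threshold minimum fraction of bins on which the two
#'   callers must agree (default 0.90).
#' @param min_reads_per_bin_per_copy library-depth floor (default 5).
#' @param alpha permutation significance level for accepting a change point
#'   (default 0.003). The level balances two failure modes of the structural
#'   score, which counts every copy-number transition: with two detectors
#'   scanning ~22 chromosomes per cell, a looser level lets spurious change
#'   points inflate the breakpoint count, while a tighter one misses real
#'   segmental events sitting near the power floor of shallow coverage
#'   (gains on already-amplified chromosomes are the weakest signals).
#'   1,000 permutations resolve p = 1/1001 below this level.
#' @param min_seg_len minimum segment length in bins (default 2).
#' @param max_copy upper bound of the copy-scale search (default 8).
#' @param nperm permutations per change-point test (default 1000).
#' @param seed optional seed governing the permutation tests; each cell in
#'   [call_and_curate()] uses `seed + cell index`.
#' @return A list of class `"caller_params"`.
#' @export
caller_params <- function(concordance_threshold = 0.90,
                          min_reads_per_bin_per_copy = 5,
                          alpha = 0.003,
                          min_seg_len = 2L,
                          max_copy = 8L,
                          nperm = 1000L,
                          seed = NULL) {
  assert_that(concordance_threshold > 0 && concordance_threshold <= 1,
              "concordance_threshold must lie in (0, 1]")
  assert_that(min_reads_per_bin_per_copy > 0,
              "min_reads_per_bin_per_copy must be > 0")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  assert_that(min_seg_len >= 1, "min_seg_len must be >= 1")
  structure(list(concordance_threshold = concordance_threshold,
                 min_reads_per_bin_per_copy = min_reads_per_bin_per_copy,
                 alpha = alpha, min_seg_len = as.integer(min_seg_len),
                 max_copy = as.integer(max_copy), nperm = as.integer(nperm),
                 seed = seed),
            class = "caller_params")
}

# Recursive change-point search on one chromosome's track. At each step the
# two-boundary segment (inner bins vs complement) maximizing the method's
# statistic is tested against its permutation null; the boundaries of a
# significant segment become change points and all resulting parts are
# revisited.
segment_recurse <- function(x, offset, params, method) {
  n <- length(x)
  if (n < 2 * params$min_seg_len) return(integer())
  if (max(x) - min(x) < .Machine$double.eps * (1 + abs(max(x))))
    return(integer())  # constant track
  best <- cpp_best_segment(x, params$min_seg_len, method)
  if (best$i < 0 || best$stat <= 0) return(integer())
  pval <- cpp_perm_pvalue(x, params$min_seg_len, params$nperm, method,
                          best$stat, params$alpha)
  if (pval >= params$alpha) return(integer())
  i <- best$i; j <- best$j
  cps <- integer()
  if (i > 1) {
    cps <- c(cps, offset + i - 1L,
             segment_recurse(x[seq_len(i - 1L)], offset, params, method))
  }
  cps <- c(cps, segment_recurse(x[i:j], offset + i - 1L, params, method))
  if (j < n) {
    cps <- c(cps, offset + j,
             segment_recurse(x[(j + 1L):n], offset + j, params, method))
  }
  sort(cps)
}

segment_track <- function(cell_track, params, chrom, method) {
  stopifnot(inherits(params, "caller_params"))
  assert_that(is.numeric(cell_track) && length(cell_track) >= 1,
              "cell_track must be a non-empty numeric vector")
  if (is.null(chrom)) chrom <- rep("chr", length(cell_track))
  assert_that(length(chrom) == length(cell_track),
              "chrom must annotate every bin of the track")
  run <- function() {
    cps <- integer()
    # chromosomes occupy contiguous index ranges in map order
    idx_by_chrom <- split(seq_along(cell_track), factor(chrom, levels = unique(chrom)))
    for (idx in idx_by_chrom) {
      cps <- c(cps, segment_recurse(cell_track[idx], idx[1] - 1L, params, method))
    }
    sort(unique(as.integer(cps)))
  }
  if (!is.null(params$seed)) with_seed(params$seed, run()) else run()
}

#' Recursive binary t-segmentation of a per-cell track
#'
#' CBS-style change-point detection: within each chromosome, recursively
#' find the two-boundary segment (inner bins against their complement, as in
#' circular binary segmentation; single splits are the edge cases) that
#' maximizes the two-sample t statistic, and keep its boundaries if the
#' permutation p-value beats `params$alpha`. A change point at index k marks
#' the boundary after the k-th bin of the track; chromosome boundaries are
#' never reported as change points.
#'
#' @param cell_track numeric per-bin signal (GC-corrected counts) in bin-map
#'   order.
#' @param params a [caller_params()].
#' @param chrom optional chromosome label per bin; segmentation never crosses
#'   a chromosome boundary. Omitted = single chromosome.
#' @return Strictly increasing integer vector of change-point indices.
#' @export
segment_binary <- function(cell_track, params = caller_params(), chrom = NULL) {
  segment_track(cell_track, params, chrom, "t")
}

#' E-divisive energy-statistic segmentation of a per-cell track
#'
#' Hierarchical change-point detection using the between-sample energy
#' distance `m*n/(m+n) * (2*E|X-Y| - E|X-X'| - E|Y-Y'|)` with permutation
#' significance; output contract identical to [segment_binary()].
#'
#' @inheritParams segment_binary
#' @return Strictly increasing integer vector of change-point indices.
#' @export
segment_edivisive <- function(cell_track, params = caller_params(), chrom = NULL) {
  segment_track(cell_track, params, chrom, "energy")
}
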