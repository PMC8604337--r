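#' Karyotype instability scores
#'
#' Three statistics summarize a curated single-cell population:
#'
#' * **Aneuploidy** — per cell, the bin-width-weighted mean of
#'   `|copy - euploid_copy|`; per sample, the unweighted mean over cells.
#'   Measures the static deviation from the euploid state.
#' * **Heterogeneity** — per bin, the proportion of the `n(n-1)/2` unordered
#'   cell pairs with unequal copy; per sample, the bin-width-weighted mean of
#'   those proportions. Measures cell-to-cell karyotype variation, the
#'   signature of ongoing instability.
#' * **Structural** — per cell, the number of copy-number transitions between
#'   consecutive bins of the same chromosome, divided by the total genome
#'   length in Mb (the union span of non-blacklisted bins); per sample, the
#'   unweighted mean over cells. Measures sub-chromosomal rearrangement.
#'
#' Sex chromosomes (X/Y) are excluded by default, matching the autosomal
#' framing of the cohort analysis; pass `autosomes_only = FALSE` to keep
#' them.
#'
#' @name karyotype-scores
NULL

score_bins <- function(binmap, autosomes_only = TRUE) {
  keep <- !binmap$blacklisted
  if (autosomes_only) {
    sex <- sub("^chr", "", binmap$chrom, ignore.case = TRUE) %in%
      c("X", "Y", "x", "y")
    keep <- keep & !sex
  }
  assert_that(any(keep), "no scorable bins left after filtering")
  keep
}

#' Per-cell aneuploidy score
#'
#' Bin-width-weighted mean absolute deviation of the copy state from the
#' euploid expectation over non-blacklisted (by default autosomal) bins.
#'
#' @param profile integer copy vector over the bin map.
#' @param binmap a [bin_map()].
#' @param euploid_copy expected copy number when euploid (default 2).
#' @param autosomes_only drop X/Y bins before scoring (default TRUE).
#' @return Non-negative real.
#' @export
cell_aneuploidy <- function(profile, binmap, euploid_copy = 2,
                            autosomes_only = TRUE) {
  assert_that(length(profile) == nrow(binmap),
              "profile must cover the bin map")
  keep <- score_bins(binmap, autosomes_only)
  w <- bin_widths(binmap)[keep]
  sum(w * abs(profile[keep] - euploid_copy)) / sum(w)
}

#' Sample aneuploidy score
#'
#' Unweighted mean of [cell_aneuploidy()] over the population's cells.
#'
#' @param population a [cell_population()].
#' @inheritParams cell_aneuploidy
#' @return Non-negative real.
#' @export
sample_aneuploidy <- function(population, euploid_copy = 2,
                              autosomes_only = TRUE) {
  stopifnot(inherits(population, "cell_population"))
  mean(apply(population$profiles, 2, cell_aneuploidy,
             binmap = population$binmap, euploid_copy = euploid_copy,
             autosomes_only = autosomes_only))
}

#' Sample heterogeneity score
#'
#' Per bin, the proportion of unordered cell pairs that differ in copy
#' number; the sample score is the bin-width-weighted average over bins.
#' Unequal-pair counts are computed from the per-bin copy-state tally:
#' `C(n,2) - sum_v C(n_v, 2)`.
#'
#' @inheritParams sample_aneuploidy
#' @return Real in \[0, 1\].
#' @export
sample_heterogeneity <- function(population, autosomes_only = TRUE) {
  stopifnot(inherits(population, "cell_population"))
  n <- ncol(population$profiles)
  assert_that(n >= 2, "heterogeneity requires at least 2 cells")
  keep <- score_bins(population$binmap, autosomes_only)
  prof <- population$profiles[keep, , drop = FALSE]
  w <- bin_widths(population$binmap)[keep]
  total_pairs <- n * (n - 1) / 2
  bin_prop <- apply(prof, 1, function(copies) {
    tab <- tabulate(factor(copies))
    (total_pairs - sum(tab * (tab - 1) / 2)) / total_pairs
  })
  sum(w * bin_prop) / sum(w)
}

#' Per-cell structural score (breakpoints per Mb)
#'
#' Copy-number transitions between consecutive bins of the same chromosome,
#' divided by the total genome length in Mb (union span of the scored bins).
#' Single-bin chromosomes contribute no transitions; transitions are never
#' counted across chromosome boundaries.
#'
#' @inheritParams cell_aneuploidy
#' @return Non-negative real.
#' @export
cell_structural <- function(profile, binmap, autosomes_only = TRUE) {
  assert_that(length(profile) == nrow(binmap),
              "profile must cover the bin map")
  keep <- score_bins(binmap, autosomes_only)
  prof <- profile[keep]
  chrom <- binmap$chrom[keep]
  same_chrom <- chrom[-1] == chrom[-length(chrom)]
  transitions <- sum(prof[-1] != prof[-length(prof)] & same_chrom)
  genome_mb <- union_span_bp(binmap[keep, , drop = FALSE]) / 1e6
  transitions / genome_mb
}

# total span of the union of bins, in bp (robust to overlapping bins)
union_span_bp <- function(bm) {
  total <- 0
  for (ch in unique(bm$chrom)) {
    b <- bm[bm$chrom == ch, , drop = FALSE]
    b <- b[order(b$start, b$end), , drop = FALSE]
    cur_s <- b$start[1]; cur_e <- b$end[1]
    if (nrow(b) > 1) for (i in 2:nrow(b)) {
      if (b$start[i] <= cur_e) cur_e <- max(cur_e, b$end[i])
      else { total <- total + cur_e - cur_s; cur_s <- b$start[i]; cur_e <- b$end[i] }
    }
    total <- total + cur_e - cur_s
  }
  total
}

#' Sample structural score
#'
#' Unweighted mean of [cell_structural()] over cells.
#'
#' @inheritParams sample_aneuploidy
#' @return Non-negative real.
#' @export
sample_structural <- function(population, autosomes_only = TRUE) {
  stopifnot(inherits(population, "cell_population"))
  mean(apply(population$profiles, 2, cell_structural,
             binmap = population$binmap, autosomes_only = autosomes_only))
}

#' Score a cell population
#'
#' Bundles the three sample-level instability scores and the per-cell score
#' vectors; deterministic.
#'
#' @inheritParams sample_aneuploidy
#' @return A list of class `"karyotype_scores"`: `sample_id`, `n_cells`,
#'   `aneuploidy`, `heterogeneity`, `structural`, `per_cell` (data.frame of
#'   per-cell aneuploidy and structural scores), `euploid_reference_copy`,
#'   and `genome_mb` (the structural denominator).
#' @export
score_sample <- function(population, euploid_copy = 2, autosomes_only = TRUE) {
  stopifnot(inherits(population, "cell_population"))
  assert_that(ncol(population$profiles) >= 2,
              "scoring requires at least 2 cells")
  keep <- score_bins(population$binmap, autosomes_only)
  per_cell <- data.frame(
    cell = population$cell_ids,
    aneuploidy = apply(population$profiles, 2, cell_aneuploidy,
                       binmap = population$binmap, euploid_copy = euploid_copy,
                       autosomes_only = autosomes_only),
    structural = apply(population$profiles, 2, cell_structural,
                       binmap = population$binmap,
                       autosomes_only = autosomes_only),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    sample_id = population$sample_id,
    n_cells = ncol(population$profiles),
    aneuploidy = mean(per_cell$aneuploidy),
    heterogeneity = sample_heterogeneity(population, autosomes_only),
    structural = mean(per_cell$structural),
    per_cell = per_cell,
    euploid_reference_copy = euploid_copy,
    genome_mb = union_span_bp(population$binmap[keep, , drop = FALSE]) / 1e6
  ), class = "karyotype_scores")
}

#' @export
print.karyotype_scores <- function(x, ...) {
  cat(sprintf(
    "KaryotypeScores '%s' (%d cells): aneuploidy %.4f, heterogeneity %.4f, structural %.4f /Mb\n",
    x$sample_id, x$n_cells, x$aneuploidy, x$heterogeneity, x$structural))
  invisible(x)
}
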