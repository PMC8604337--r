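#' Integerize a segmented track into copy numbers
#'
#' Grid-searches a reads-per-copy scale factor over candidates derived from
#' the segment means (`mean / c` for every integer copy `c` up to
#' `params$max_copy`), minimizing the bin-width-weighted squared distance of
#' scaled segment means to their nearest non-negative integers. Ties in the
#' fit are broken toward the scale whose genome-wide median copy is closest
#' to 2 (euploid reference), then toward the larger scale (lower ploidy).
#'
#' @param cell_track numeric per-bin signal in bin-map order.
#' @param change_points strictly increasing change-point indices as returned
#'   by the segmenters; chromosome boundaries may be included to keep
#'   segments chromosome-local.
#' @param params a [caller_params()].
#' @param widths optional per-bin widths used as weights (default: equal).
#' @return Integer copy number per bin, with the optimal scale in
#'   `attr(, "scale")` (reads per copy; NA for all-zero tracks).
#' @export
assign_copy_numbers <- function(cell_track, change_points,
                                params = caller_params(), widths = NULL) {
  n <- length(cell_track)
  assert_that(n >= 1, "cell_track must be non-empty")
  if (is.null(widths)) widths <- rep(1, n)
  assert_that(length(widths) == n, "widths must match the track length")
  cp <- sort(unique(as.integer(change_points)))
  assert_that(all(cp >= 1 & cp < n), "change points must lie inside the track")
  bounds <- c(0L, cp, n)
  seg_id <- rep(seq_len(length(bounds) - 1L), diff(bounds))
  seg_w <- as.vector(tapply(widths, seg_id, sum))
  seg_mean <- as.vector(tapply(cell_track * widths, seg_id, sum)) / seg_w

  if (all(seg_mean < .Machine$double.eps)) {
    out <- rep(0L, n)
    attr(out, "scale") <- NA_real_
    return(out)
  }

  # Candidate scales: every segment mean divided by every admissible copy
  # number. The fit error is measured in read space, sum_s w_s (m_s - s*c_s)^2,
  # where harmonic scales (r, r/2, r/3, ...) of a good reads-per-copy r fit
  # equally well up to sampling noise; a copy-space error would instead
  # always favor the largest scale. Scales whose error is within the noise
  # floor of the best fit (the error expected when the scale is right, from
  # within-segment variance) are treated as tied, and ties go to the scale
  # whose genome-wide median copy is closest to 2, then to the larger scale.
  nearest <- function(x) pmax(floor(x + 0.5), 0)
  seg_n <- as.vector(table(seg_id))
  seg_var <- as.vector(tapply(cell_track, seg_id, stats::var)) / seg_n
  if (all(is.na(seg_var))) seg_var[] <- 0
  seg_var[is.na(seg_var)] <- median(seg_var, na.rm = TRUE)
  noise_floor <- sum(seg_w * seg_var)

  cand <- unlist(lapply(seg_mean[seg_mean > 0], function(m) m / seq_len(params$max_copy)))
  cand <- sort(unique(signif(cand, 12)), decreasing = TRUE)
  fits <- lapply(cand, function(s) {
    copies <- nearest(seg_mean / s)
    list(s = s, copies = copies,
         err = sum(seg_w * (seg_mean - s * copies)^2),
         med_dist = abs(median(copies[seg_id]) - 2))
  })
  errs <- vapply(fits, `[[`, numeric(1), "err")
  tol <- max(min(errs) * 1e-9, 4 * noise_floor)
  tied <- fits[errs <= min(errs) + tol]
  med <- vapply(tied, `[[`, numeric(1), "med_dist")
  tied <- tied[med == min(med)]
  best <- tied[[which.max(vapply(tied, `[[`, numeric(1), "s"))]]
  out <- as.integer(best$copies[seg_id])
  attr(out, "scale") <- best$s
  out
}

#' Bin-wise concordance between two copy-number profiles
#'
#' Fraction of non-blacklisted bins with identical integer copy state;
#' symmetric in its arguments.
#'
#' @param profile_a,profile_b integer copy vectors on the same bin map.
#' @param blacklisted optional logical mask of bins to exclude.
#' @return Fraction in \[0, 1\].
#' @export
concordance <- function(profile_a, profile_b, blacklisted = NULL) {
  assert_that(length(profile_a) == length(profile_b),
              "profiles are on different bin maps")
  keep <- if (is.null(blacklisted)) rep(TRUE, length(profile_a)) else !blacklisted
  assert_that(length(keep) == length(profile_a) && any(keep),
              "blacklist mask must match the profiles and leave bins")
  mean(profile_a[keep] == profile_b[keep])
}

# The curation rule: a cell fails on concordance strictly below the
# threshold, then on library depth strictly below the floor ("less than 5
# reads per bin per copy" is discarded, exactly 5 is kept).
curation_decision <- function(conc, mrpc, params) {
  if (conc < params$concordance_threshold) {
    list(pass = FALSE, reason = "low-concordance")
  } else if (mrpc < params$min_reads_per_bin_per_copy) {
    list(pass = FALSE, reason = "low-coverage")
  } else {
    list(pass = TRUE, reason = "")
  }
}

#' Call and curate single-cell copy-number profiles
#'
#' Per cell: GC-correct, segment with both the recursive binary t-detector
#' and the e-divisive energy detector, integerize each segmentation, and
#' curate: a cell is discarded when the two profiles agree on fewer than
#' `concordance_threshold` of bins, or when its library depth — raw reads
#' over retained bins divided by the sum of called copies (from the
#' e-divisive profile) — is strictly below `min_reads_per_bin_per_copy`.
#' The reported profile of a surviving cell is the e-divisive-derived one.
#'
#' @param counts a [read_count_matrix()].
#' @param binmap bin map (defaults to the one bound to `counts`).
#' @param params a [caller_params()].
#' @return A list: `population` (a [cell_population()] of passing cells, or
#'   `NULL` with a warning if none pass) and `qc`, a per-cell data.frame with
#'   columns `cell`, `concordance`, `mean_reads_per_bin_per_copy`, `pass`,
#'   `reason` (`""`, `"low-concordance"`, `"low-coverage"` or `"zero-copy"`).
#' @export
call_and_curate <- function(counts, binmap = counts$binmap,
                            params = caller_params()) {
  stopifnot(inherits(counts, "read_counts"), inherits(params, "caller_params"))
  corrected <- gc_correct(counts, binmap)
  bm <- corrected$binmap
  raw <- counts$counts[!binmap$blacklisted, , drop = FALSE]
  widths <- bin_widths(bm)
  chrom <- bm$chrom
  chrom_bounds <- cumsum(rle(chrom)$lengths)
  chrom_bounds <- chrom_bounds[-length(chrom_bounds)]

  n_cells <- ncol(corrected$counts)
  profiles <- matrix(NA_integer_, nrow(bm), n_cells)
  qc <- data.frame(cell = colnames(corrected$counts),
                   concordance = NA_real_,
                   mean_reads_per_bin_per_copy = NA_real_,
                   pass = FALSE, reason = "", stringsAsFactors = FALSE)
  for (j in seq_len(n_cells)) {
    p_j <- params
    if (!is.null(params$seed)) p_j$seed <- params$seed + j
    track <- corrected$counts[, j]
    cps_b <- segment_binary(track, p_j, chrom)
    cps_e <- segment_edivisive(track, p_j, chrom)
    prof_b <- assign_copy_numbers(track, union(cps_b, chrom_bounds), params, widths)
    prof_e <- assign_copy_numbers(track, union(cps_e, chrom_bounds), params, widths)
    conc <- concordance(prof_b, prof_e)
    total_copies <- sum(as.numeric(prof_e))
    qc$concordance[j] <- conc
    if (total_copies == 0) {
      qc$reason[j] <- "zero-copy"
      next
    }
    mrpc <- sum(raw[, j]) / total_copies
    qc$mean_reads_per_bin_per_copy[j] <- mrpc
    decision <- curation_decision(conc, mrpc, params)
    qc$reason[j] <- decision$reason
    if (decision$pass) {
      qc$pass[j] <- TRUE
      profiles[, j] <- prof_e
    }
  }
  if (!any(qc$pass)) {
    warning("no cell passed curation")
    return(list(population = NULL, qc = qc))
  }
  keep <- which(qc$pass)
  pop <- cell_population(bm, profiles[, keep, drop = FALSE],
                         sample_id = "curated")
  colnames(pop$profiles) <- qc$cell[keep]
  pop$cell_ids <- qc$cell[keep]
  list(population = pop, qc = qc)
}
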