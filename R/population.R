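#' Cell populations
#'
#' A cell population couples a [bin_map()] with one integer copy-number
#' profile per cell (bins x cells matrix). Populations come either from the
#' simulator ([simulate_population()], where the profiles are ground truth)
#' or from curation of read counts ([call_and_curate()]).
#'
#' @param binmap a [bin_map()].
#' @param profiles integer matrix, bins x cells, copy state per bin.
#' @param sample_id sample label.
#' @param clone optional per-cell clone label (simulator ground truth).
#' @return An object of class `"cell_population"`.
#' @export
cell_population <- function(binmap, profiles, sample_id = "sample",
                            clone = NULL) {
  profiles <- as.matrix(profiles)
  assert_that(nrow(profiles) == nrow(binmap),
              "profiles must have one row per bin in the bin map")
  assert_that(ncol(profiles) >= 1L, "population must contain at least one cell")
  assert_that(all(profiles >= 0) && !anyNA(profiles),
              "copy states must be complete and >= 0")
  if (is.null(colnames(profiles)))
    colnames(profiles) <- sprintf("cell_%03d", seq_len(ncol(profiles)))
  structure(list(binmap = binmap, profiles = profiles,
                 cell_ids = colnames(profiles), sample_id = sample_id,
                 clone = clone),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("CellPopulation '%s': %d cells x %d bins (%d chromosomes)\n",
              x$sample_id, ncol(x$profiles), nrow(x$binmap),
              length(unique(x$binmap$chrom))))
  invisible(x)
}

#' Simulation configuration for clonal cell populations
#'
#' Describes a tumor-like population: a founder clone carrying shared clonal
#' events (optionally whole-genome duplicated), optional discrete subclones,
#' and ongoing per-cell chromosome missegregation and segmental events that
#' produce intratumor karyotype heterogeneity.
#'
#' @param n_cells number of cells (>= 1).
#' @param chromosome_lengths named vector, chromosome name -> length (bp).
#' @param bin_width bin width in bp.
#' @param base_ploidy founder copy number before any event (default 2).
#' @param wgd_probability probability that the founder undergoes whole-genome
#'   duplication (applied after the clonal founder events).
#' @param founder_event_count number of clonal whole-chromosome gain/loss
#'   events shared by every founder-clone cell.
#' @param missegregation_rate expected whole-chromosome gain/loss events per
#'   cell (Poisson).
#' @param segmental_rate expected segmental (sub-chromosomal) +/-1 events per
#'   cell (Poisson); each picks a uniform breakpoint pair within one
#'   chromosome, subject to `min_segment_length`.
#' @param min_segment_length minimum segmental-event size in bp (default
#'   15 Mb). Tumor segmental aneuploidies are typically chromosome-arm
#'   scale, and events much below this are unresolvable by megabase-binned
#'   shallow sequencing anyway; breakpoint pairs are drawn uniformly among
#'   pairs at least this far apart.
#' @param subclone_fractions optional list of subclones, each
#'   `list(fraction =, events =)` where `events` is a data.frame with columns
#'   `chrom`, `start`, `end`, `delta` (`NA` start/end = whole chromosome).
#'   Fractions must sum to <= 1; the remainder of cells is the founder clone.
#' @param seed RNG seed.
#' @return A list of class `"population_sim_config"`.
#' @export
population_sim_config <- function(n_cells,
                                  chromosome_lengths,
                                  bin_width = 1e6,
                                  base_ploidy = 2L,
                                  wgd_probability = 0,
                                  founder_event_count = 0L,
                                  missegregation_rate = 0,
                                  segmental_rate = 0,
                                  min_segment_length = 15e6,
                                  subclone_fractions = NULL,
                                  seed = 1L) {
  assert_that(is.numeric(n_cells) && n_cells >= 1, "n_cells must be >= 1")
  assert_that(length(chromosome_lengths) >= 1, "genome must be non-empty")
  assert_that(bin_width > 0, "bin_width must be > 0")
  assert_that(base_ploidy >= 0, "base_ploidy must be >= 0")
  assert_that(wgd_probability >= 0 && wgd_probability <= 1,
              "wgd_probability must lie in [0, 1]")
  assert_that(missegregation_rate >= 0 && segmental_rate >= 0 &&
                founder_event_count >= 0, "all event rates must be >= 0")
  if (!is.null(subclone_fractions)) {
    fr <- vapply(subclone_fractions, function(s) s$fraction, numeric(1))
    assert_that(all(fr >= 0) && sum(fr) <= 1,
                "subclone fractions must be >= 0 and sum to <= 1")
  }
  structure(list(n_cells = as.integer(n_cells),
                 chromosome_lengths = chromosome_lengths,
                 bin_width = bin_width, base_ploidy = as.integer(base_ploidy),
                 wgd_probability = wgd_probability,
                 founder_event_count = as.integer(founder_event_count),
                 missegregation_rate = missegregation_rate,
                 segmental_rate = segmental_rate,
                 min_segment_length = min_segment_length,
                 subclone_fractions = subclone_fractions,
                 seed = as.integer(seed)),
            class = "population_sim_config")
}

# Apply an event table (chrom, start, end, delta; NA coords = whole
# chromosome) to a per-bin profile vector. Copy numbers are clamped at 0.
apply_events <- function(profile, binmap, events) {
  if (is.null(events) || nrow(events) == 0) return(profile)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    sel <- binmap$chrom == ev$chrom
    if (!is.na(ev$start)) sel <- sel & binmap$end > ev$start
    if (!is.na(ev$end)) sel <- sel & binmap$start < ev$end
    profile[sel] <- profile[sel] + ev$delta
  }
  pmax(profile, 0)
}

# One random whole-chromosome +/-1 event that keeps the profile >= 0;
# losses that would push any affected bin below zero are resampled.
draw_whole_chrom_event <- function(profile, binmap, chroms, max_tries = 20L) {
  for (i in seq_len(max_tries)) {
    ch <- sample(chroms, 1)
    delta <- sample(c(-1L, 1L), 1)
    sel <- binmap$chrom == ch
    if (all(profile[sel] + delta >= 0))
      return(list(sel = sel, delta = delta))
  }
  NULL
}

draw_segmental_event <- function(profile, binmap, chroms, min_bins = 1L,
                                 max_tries = 20L) {
  for (i in seq_len(max_tries)) {
    ch <- sample(chroms, 1)
    idx <- which(binmap$chrom == ch)
    if (length(idx) < min_bins + 1L) next
    # uniform breakpoint pair on the bin boundaries of this chromosome
    bp <- sort(sample(seq_len(length(idx) + 1L) - 1L, 2))
    if (bp[2] - bp[1] < min_bins) next
    sel_local <- idx[(bp[1] + 1L):bp[2]]
    if (length(sel_local) == length(idx)) next  # whole chromosome, not segmental
    delta <- sample(c(-1L, 1L), 1)
    if (all(profile[sel_local] + delta >= 0)) {
      sel <- rep(FALSE, nrow(binmap)); sel[sel_local] <- TRUE
      return(list(sel = sel, delta = delta))
    }
  }
  NULL
}

#' Simulate a clonal cell population with ongoing instability
#'
#' Builds the bin map from the configured genome, constructs a founder
#' karyotype (base ploidy, clonal whole-chromosome events, optional
#' whole-genome duplication), carves out any configured subclones, and then
#' draws independent per-cell missegregation and segmental events. The
#' returned profiles are ground truth for the downstream caller and scores.
#'
#' GC content per bin is drawn once per bin map (Beta-distributed around
#' 0.45) so that read-count simulation can impose a GC bias.
#'
#' @param config a [population_sim_config()].
#' @return A [cell_population()]; `$clone` holds ground-truth clone labels.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "population_sim_config"))
  with_seed(config$seed, {
    binmap <- make_bins(config$chromosome_lengths, config$bin_width)
    binmap$gc <- round(rbeta(nrow(binmap), 50, 60), 4)
    chroms <- unique(binmap$chrom)
    nb <- nrow(binmap)

    founder <- rep(config$base_ploidy, nb)
    for (i in seq_len(config$founder_event_count)) {
      ev <- draw_whole_chrom_event(founder, binmap, chroms)
      if (!is.null(ev)) founder[ev$sel] <- founder[ev$sel] + ev$delta
    }
    if (config$wgd_probability > 0 && runif(1) < config$wgd_probability)
      founder <- founder * 2L

    # clone assignment: subclones take the first floor(fraction * n) cells
    clone <- rep("founder", config$n_cells)
    clone_profiles <- list(founder = founder)
    if (!is.null(config$subclone_fractions)) {
      nxt <- 1L
      for (k in seq_along(config$subclone_fractions)) {
        sc <- config$subclone_fractions[[k]]
        n_k <- floor(sc$fraction * config$n_cells)
        if (n_k == 0) next
        lab <- sprintf("subclone_%d", k)
        clone[nxt:(nxt + n_k - 1L)] <- lab
        clone_profiles[[lab]] <- apply_events(founder, binmap, sc$events)
        nxt <- nxt + n_k
      }
    }

    profiles <- matrix(0L, nb, config$n_cells)
    for (j in seq_len(config$n_cells)) {
      p <- clone_profiles[[clone[j]]]
      n_mis <- if (config$missegregation_rate > 0)
        rpois(1, config$missegregation_rate) else 0L
      for (i in seq_len(n_mis)) {
        ev <- draw_whole_chrom_event(p, binmap, chroms)
        if (!is.null(ev)) p[ev$sel] <- p[ev$sel] + ev$delta
      }
      n_seg <- if (config$segmental_rate > 0)
        rpois(1, config$segmental_rate) else 0L
      min_bins <- max(1L, ceiling(config$min_segment_length / config$bin_width))
      for (i in seq_len(n_seg)) {
        ev <- draw_segmental_event(p, binmap, chroms, min_bins)
        if (!is.null(ev)) p[ev$sel] <- p[ev$sel] + ev$delta
      }
      profiles[, j] <- as.integer(p)
    }
    cell_population(binmap, profiles, sample_id = "simulated", clone = clone)
  })
}
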