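#' Spectral-count tables
#'
#' Long-format label-free quantification data: one row per (protein,
#' condition, replicate) with its spectral count. Conditions are the fixed
#' FLAG-IP design: `EV` (empty-vector background pull-down), `WT`
#' (FLAG-H3.3 wild type) and `K27M` (FLAG-H3.3K27M). The anchor protein
#' (histone H4 by default) tracks nucleosomal pull-down yield.
#'
#' @param df data.frame with columns `protein`, `condition`, `replicate`,
#'   `spec_count`.
#' @param anchor anchor protein identifier (default `"H4"`).
#' @return `df` validated, classed `"spectral_counts"`, with the anchor in
#'   `attr(, "anchor")`.
#' @export
spectral_count_table <- function(df, anchor = "H4") {
  need <- c("protein", "condition", "replicate", "spec_count")
  assert_that(all(need %in% names(df)),
              paste("spectral-count table needs columns:",
                    paste(need, collapse = ", ")))
  assert_that(all(df$condition %in% c("EV", "WT", "K27M")),
              "conditions must be drawn from {EV, WT, K27M}")
  assert_that(all(df$spec_count >= 0), "spectral counts must be >= 0")
  df <- as.data.frame(df)[, need]
  attr(df, "anchor") <- anchor
  class(df) <- c("spectral_counts", "data.frame")
  df
}

#' Spectral-count simulation configuration
#'
#' Emulates the statistical structure of a three-condition FLAG-IP
#' spectral-count experiment: sticky background proteins present in every
#' pull-down, bait-specific interactors present only where their bait is,
#' shared interactors present with both baits, and an H4 anchor tracking
#' nucleosome yield. Counts are Poisson.
#'
#' @param n_background_proteins proteins at `background_mean` in all three
#'   conditions (nonspecific binders).
#' @param n_wt_specific,n_k27m_specific,n_shared bait-specific interactor
#'   counts; these proteins are absent (structural zero) from pull-downs
#'   lacking their bait, including EV.
#' @param n_replicates_per_condition technical replicates per condition
#'   (default 4).
#' @param background_mean expected background spectral count.
#' @param effect_mean expected bait-specific spectral count.
#' @param h4_mean_per_condition named vector, expected H4 count per
#'   condition; bait conditions should exceed EV for replicate QC to retain
#'   them.
#' @param seed RNG seed.
#' @return A list of class `"spectra_sim_config"`.
#' @export
spectra_sim_config <- function(n_background_proteins = 20L,
                               n_wt_specific = 5L,
                               n_k27m_specific = 5L,
                               n_shared = 5L,
                               n_replicates_per_condition = 4L,
                               background_mean = 1,
                               effect_mean = 10,
                               h4_mean_per_condition = c(EV = 10, WT = 40, K27M = 30),
                               seed = 1L) {
  assert_that(n_replicates_per_condition >= 1L,
              "at least one replicate per condition is required")
  assert_that(all(c(n_background_proteins, n_wt_specific, n_k27m_specific,
                    n_shared) >= 0), "protein class sizes must be >= 0")
  assert_that(background_mean > 0 || n_background_proteins == 0,
              "background_mean must be > 0 when background proteins exist")
  assert_that(effect_mean >= 0, "effect_mean must be >= 0")
  assert_that(all(c("EV", "WT", "K27M") %in% names(h4_mean_per_condition)) &&
                all(h4_mean_per_condition > 0),
              "h4_mean_per_condition needs positive EV, WT and K27M entries")
  structure(list(n_background_proteins = as.integer(n_background_proteins),
                 n_wt_specific = as.integer(n_wt_specific),
                 n_k27m_specific = as.integer(n_k27m_specific),
                 n_shared = as.integer(n_shared),
                 n_replicates_per_condition = as.integer(n_replicates_per_condition),
                 background_mean = background_mean, effect_mean = effect_mean,
                 h4_mean_per_condition = h4_mean_per_condition,
                 seed = as.integer(seed)),
            class = "spectra_sim_config")
}

#' Simulate a FLAG-IP spectral-count table with ground truth
#'
#' @param config a [spectra_sim_config()].
#' @return A list: `table` (a [spectral_count_table()]) and `truth`, a
#'   data.frame of designed per-protein labels in
#'   \{`background-only`, `WT-unique`, `K27M-unique`, `common`\}. Zero counts
#'   for non-anchor proteins are omitted from the table, as in real LFQ
#'   output; the anchor is reported in every replicate.
#' @export
simulate_spectral_counts <- function(config) {
  stopifnot(inherits(config, "spectra_sim_config"))
  mk <- function(n, prefix) if (n > 0) sprintf("%s_%03d", prefix, seq_len(n)) else character()
  bg <- mk(config$n_background_proteins, "BG")
  wts <- mk(config$n_wt_specific, "WTSP")
  kms <- mk(config$n_k27m_specific, "KMSP")
  sh <- mk(config$n_shared, "SHARED")
  truth <- data.frame(
    protein = c(bg, wts, kms, sh),
    truth = c(rep("background-only", length(bg)),
              rep("WT-unique", length(wts)),
              rep("K27M-unique", length(kms)),
              rep("common", length(sh))),
    stringsAsFactors = FALSE
  )
  conds <- c("EV", "WT", "K27M")
  # Bait-specific counts scale with the condition's nucleosome pull-down
  # yield (tracked by its H4 level relative to WT), which is exactly what
  # anchor normalization removes downstream. Bead background does not.
  yield <- config$h4_mean_per_condition / config$h4_mean_per_condition[["WT"]]
  mean_for <- function(protein_set, cond) {
    m <- numeric(length(protein_set))
    m[protein_set %in% bg] <- config$background_mean
    if (cond == "WT") m[protein_set %in% c(wts, sh)] <- config$effect_mean
    if (cond == "K27M")
      m[protein_set %in% c(kms, sh)] <- config$effect_mean * yield[["K27M"]]
    m
  }
  prot <- truth$protein
  with_seed(config$seed, {
    rows <- list()
    for (cond in conds) {
      mu <- mean_for(prot, cond)
      for (r in seq_len(config$n_replicates_per_condition)) {
        cnt <- rpois(length(mu), mu)
        keep <- cnt > 0
        rows[[length(rows) + 1L]] <- data.frame(
          protein = c(prot[keep], "H4"), condition = cond, replicate = r,
          spec_count = c(cnt[keep],
                         rpois(1, config$h4_mean_per_condition[[cond]])),
          stringsAsFactors = FALSE
        )
      }
    }
    list(table = spectral_count_table(do.call(rbind, rows), anchor = "H4"),
         truth = truth)
  })
}
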