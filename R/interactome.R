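#' Interactor classification parameters
#'
#' @param enrichment_delta spectral-count difference beyond which a protein
#'   present with both baits is called enriched (default 2; a difference of
#'   exactly 2 is common/not-enriched).
#' @param presence_floor post-subtraction normalized count a protein must
#'   strictly exceed to count as present in a condition (default 0).
#' @param strict_qc replicate QC keeps bait replicates whose anchor count is
#'   strictly above the mean EV anchor (default TRUE); FALSE relaxes to >=.
#' @param delta_on_normalized apply the enrichment threshold to normalized
#'   means (default TRUE) or to background-corrected unnormalized means.
#' @return A list of class `"classification_params"`.
#' @export
classification_params <- function(enrichment_delta = 2,
                                  presence_floor = 0,
                                  strict_qc = TRUE,
                                  delta_on_normalized = TRUE) {
  assert_that(enrichment_delta >= 0, "enrichment_delta must be >= 0")
  assert_that(presence_floor >= 0, "presence_floor must be >= 0")
  structure(list(enrichment_delta = enrichment_delta,
                 presence_floor = presence_floor,
                 strict_qc = strict_qc,
                 delta_on_normalized = delta_on_normalized),
            class = "classification_params")
}

anchor_of <- function(table) attr(table, "anchor") %||% "H4"

replicate_anchor_counts <- function(table, cond) {
  anchor <- anchor_of(table)
  reps <- unique(table$replicate[table$condition == cond])
  vapply(reps, function(r) {
    sel <- table$condition == cond & table$replicate == r &
      table$protein == anchor
    if (any(sel)) sum(table$spec_count[sel]) else 0
  }, numeric(1))
}

#' Replicate QC against the anchor protein
#'
#' Nucleosomal pull-down yield is tracked by the anchor (histone H4): bait
#' (WT/K27M) replicates are retained only when their anchor count exceeds
#' the background level, defined as the mean EV anchor count. EV replicates
#' are always retained.
#'
#' @param table a [spectral_count_table()].
#' @param params a [classification_params()] (controls strict vs non-strict
#'   comparison).
#' @return The filtered [spectral_count_table()].
#' @export
replicate_qc <- function(table, params = classification_params()) {
  stopifnot(inherits(table, "spectral_counts"))
  anchor <- anchor_of(table)
  ev_anchor <- table$spec_count[table$condition == "EV" & table$protein == anchor]
  assert_that(length(ev_anchor) >= 1,
              "anchor protein absent from every EV replicate")
  bg <- mean(ev_anchor)
  keep_row <- rep(TRUE, nrow(table))
  for (cond in c("WT", "K27M")) {
    reps <- unique(table$replicate[table$condition == cond])
    for (r in reps) {
      sel <- table$condition == cond & table$replicate == r
      a <- sum(table$spec_count[sel & table$protein == anchor])
      ok <- if (params$strict_qc) a > bg else a >= bg
      if (!ok) keep_row[sel] <- FALSE
    }
    if (!any(keep_row & table$condition == cond))
      stop(sprintf("no %s replicate has anchor counts above background (%.2f)",
                   cond, bg), call. = FALSE)
  }
  out <- table[keep_row, , drop = FALSE]
  spectral_count_table(out, anchor = anchor)
}

#' Per-protein, per-condition mean spectral counts
#'
#' Means are taken over the retained replicates of each condition; a protein
#' not reported in a replicate counts as 0 there (absence is a zero
#' observation, not missing data).
#'
#' @param table a (QC-filtered) [spectral_count_table()].
#' @return Data.frame with columns `protein`, `EV`, `WT`, `K27M`.
#' @export
condition_means <- function(table) {
  stopifnot(inherits(table, "spectral_counts"))
  conds <- c("EV", "WT", "K27M")
  n_reps <- vapply(conds, function(cond)
    length(unique(table$replicate[table$condition == cond])), numeric(1))
  proteins <- sort(unique(table$protein))
  out <- data.frame(protein = proteins, stringsAsFactors = FALSE)
  for (cond in conds) {
    sums <- tapply(table$spec_count[table$condition == cond],
                   factor(table$protein[table$condition == cond],
                          levels = proteins), sum)
    sums[is.na(sums)] <- 0
    out[[cond]] <- if (n_reps[[cond]] > 0) as.vector(sums) / n_reps[[cond]] else 0
  }
  out
}

#' Subtract the empty-vector background
#'
#' EV means are nonspecific pull-down background and are subtracted from the
#' bait means, clamped at zero (negative abundance is not interpretable).
#' Proteins at zero in both baits after subtraction are background-only and
#' are excluded from further classification.
#'
#' @param means output of [condition_means()].
#' @return List: `means` (columns `protein`, `WT`, `K27M`, corrected) and
#'   `background_only` (character vector of excluded proteins).
#' @export
subtract_background <- function(means) {
  assert_that(all(c("protein", "EV", "WT", "K27M") %in% names(means)),
              "means must carry EV, WT and K27M columns")
  wt <- pmax(0, means$WT - means$EV)
  km <- pmax(0, means$K27M - means$EV)
  bg <- wt == 0 & km == 0
  list(means = data.frame(protein = means$protein[!bg], WT = wt[!bg],
                          K27M = km[!bg], stringsAsFactors = FALSE),
       background_only = means$protein[bg])
}

#' Normalize bait means to the WT anchor level
#'
#' Corrects for nucleosomal content: each condition's corrected means are
#' multiplied by (WT anchor mean / that condition's anchor mean), so the WT
#' factor is exactly 1 and the K27M column is rescaled to the WT pull-down
#' yield.
#'
#' @param corrected output of [subtract_background()].
#' @param table the QC-filtered [spectral_count_table()] (source of the
#'   anchor means).
#' @return `corrected` with the `means` columns rescaled; factors stored in
#'   `attr(, "anchor_factors")`.
#' @export
normalize_to_anchor <- function(corrected, table) {
  stopifnot(inherits(table, "spectral_counts"))
  cm <- condition_means(table)
  a <- cm[cm$protein == anchor_of(table), ]
  assert_that(nrow(a) == 1 && a$WT > 0 && a$K27M > 0,
              "anchor mean must be > 0 in both WT and K27M")
  f <- c(WT = 1, K27M = a$WT / a$K27M)
  corrected$means$WT <- corrected$means$WT * f[["WT"]]
  corrected$means$K27M <- corrected$means$K27M * f[["K27M"]]
  attr(corrected, "anchor_factors") <- f
  corrected
}

#' Classify interactors into unique / common / enriched sets
#'
#' A protein present (normalized corrected mean strictly above
#' `presence_floor`) with exactly one bait is unique to it. A protein present
#' with both baits is common: not enriched when |WT - K27M| is at most
#' `enrichment_delta`, otherwise enriched for the larger side.
#'
#' @param normalized output of [normalize_to_anchor()] (or of
#'   [subtract_background()] when classifying unnormalized means).
#' @param params a [classification_params()].
#' @return A list of class `"interactor_classification"`: `proteins`
#'   (data.frame with `protein`, `WT`, `K27M`, `label`) and `venn`, the
#'   summary counts (`unique_WT`, `unique_K27M`, `common_total`,
#'   `common_not_enriched`, `enriched_WT`, `enriched_K27M`,
#'   `background_only`).
#' @export
classify_interactors <- function(normalized, params = classification_params()) {
  m <- normalized$means
  present_wt <- m$WT > params$presence_floor
  present_km <- m$K27M > params$presence_floor
  diff <- m$WT - m$K27M
  label <- ifelse(!present_wt & !present_km, "background-only",
           ifelse(present_wt & !present_km, "WT-unique",
           ifelse(!present_wt & present_km, "K27M-unique",
           ifelse(abs(diff) <= params$enrichment_delta, "common-not-enriched",
           ifelse(diff > 0, "WT-enriched", "K27M-enriched")))))
  proteins <- data.frame(protein = m$protein, WT = m$WT, K27M = m$K27M,
                         label = label, stringsAsFactors = FALSE)
  venn <- c(unique_WT = sum(label == "WT-unique"),
            unique_K27M = sum(label == "K27M-unique"),
            common_not_enriched = sum(label == "common-not-enriched"),
            enriched_WT = sum(label == "WT-enriched"),
            enriched_K27M = sum(label == "K27M-enriched"),
            background_only = sum(label == "background-only") +
              length(normalized$background_only %||% character()))
  venn <- c(venn, common_total = unname(venn["common_not_enriched"] +
                                          venn["enriched_WT"] + venn["enriched_K27M"]))
  structure(list(proteins = proteins,
                 background_only = normalized$background_only %||% character(),
                 venn = venn),
            class = "interactor_classification")
}

#' @export
print.interactor_classification <- function(x, ...) {
  v <- x$venn
  cat(sprintf(paste0(
    "InteractorClassification: %d WT-unique, %d K27M-unique, %d common",
    " (%d not enriched, %d WT-enriched, %d K27M-enriched), %d background-only\n"),
    v["unique_WT"], v["unique_K27M"], v["common_total"],
    v["common_not_enriched"], v["enriched_WT"], v["enriched_K27M"],
    v["background_only"]))
  invisible(x)
}

#' Run the full label-free interactome pipeline
#'
#' Fixed order: replicate QC -> per-condition means -> EV background
#' subtraction -> anchor normalization -> classification. Deterministic.
#'
#' @param table a [spectral_count_table()].
#' @param params a [classification_params()].
#' @return An `interactor_classification` (see [classify_interactors()]).
#' @export
run_interactome_pipeline <- function(table, params = classification_params()) {
  filtered <- replicate_qc(table, params)
  means <- condition_means(filtered)
  means <- means[means$protein != anchor_of(filtered), , drop = FALSE]
  corrected <- subtract_background(means)
  staged <- if (params$delta_on_normalized)
    normalize_to_anchor(corrected, filtered) else corrected
  classify_interactors(staged, params)
}
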