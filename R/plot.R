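#' Scatter samples by aneuploidy, structural score and heterogeneity
#'
#' Minimal instability plot: aneuploidy on x, structural score (breakpoints
#' per Mb) on y, circle area proportional to heterogeneity.
#'
#' @param scores a single `karyotype_scores` object (from [score_sample()])
#'   or a list of them.
#' @param ... further arguments passed to [graphics::plot()].
#' @return The plotted data.frame (sample, aneuploidy, structural,
#'   heterogeneity), invisibly.
#' @export
plot_karyotype_scores <- function(scores, ...) {
  if (inherits(scores, "karyotype_scores")) scores <- list(scores)
  df <- do.call(rbind, lapply(scores, function(s)
    data.frame(sample = s$sample_id, aneuploidy = s$aneuploidy,
               structural = s$structural, heterogeneity = s$heterogeneity,
               stringsAsFactors = FALSE)))
  cex <- 1 + 4 * sqrt(df$heterogeneity / max(df$heterogeneity, 1e-12))
  graphics::plot(df$aneuploidy, df$structural, cex = cex, pch = 21,
                 bg = "grey70", xlab = "aneuploidy score",
                 ylab = "structural score (breakpoints / Mb)", ...)
  graphics::text(df$aneuploidy, df$structural, labels = df$sample, pos = 3)
  invisible(df)
}
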