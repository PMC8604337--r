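#' Cohort CNA-burden simulation configuration
#'
#' Emulates a tumor cohort with per-tumor autosomal copy-number aberration
#' totals: each subtype group draws its totals from an overdispersed count
#' distribution (negative binomial; var = mu + dispersion * mu^2) around the
#' group mean.
#'
#' @param group_sizes named vector, subtype label -> number of tumors
#'   (>= 2 per group so groups can be compared).
#' @param group_cna_means named vector, subtype label -> expected autosomal
#'   CNA total; names must match `group_sizes`.
#' @param dispersion negative-binomial overdispersion (0 = Poisson).
#' @param seed RNG seed.
#' @return A list of class `"burden_sim_config"`.
#' @export
burden_sim_config <- function(group_sizes, group_cna_means,
                              dispersion = 0.3, seed = 1L) {
  assert_that(length(group_sizes) >= 1 && !is.null(names(group_sizes)),
              "group_sizes must be a named vector")
  assert_that(all(group_sizes >= 2), "each group needs at least 2 tumors")
  assert_that(setequal(names(group_sizes), names(group_cna_means)),
              "group_cna_means must name the same groups as group_sizes")
  assert_that(all(group_cna_means >= 0) && dispersion >= 0,
              "group means and dispersion must be >= 0")
  structure(list(group_sizes = group_sizes,
                 group_cna_means = group_cna_means,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "burden_sim_config")
}

#' Simulate per-tumor autosomal CNA burden totals
#'
#' @param config a [burden_sim_config()].
#' @return A data.frame of class `"cna_burden"` with columns `tumor`,
#'   `subtype`, `total` (pre-summed per-tumor autosomal CNA counts).
#' @export
simulate_cna_burden <- function(config) {
  stopifnot(inherits(config, "burden_sim_config"))
  with_seed(config$seed, {
    out <- lapply(names(config$group_sizes), function(g) {
      n <- config$group_sizes[[g]]
      data.frame(tumor = sprintf("%s_T%03d", g, seq_len(n)), subtype = g,
                 total = rnbinom_md(n, rep(config$group_cna_means[[g]], n),
                                    config$dispersion),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    class(df) <- c("cna_burden", "data.frame")
    df
  })
}
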