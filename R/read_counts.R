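#' Binned read-count matrices
#'
#' Non-negative integer read counts per (bin, cell), bound to a bin map.
#'
#' @param binmap a [bin_map()].
#' @param counts bins x cells matrix of non-negative counts.
#' @return An object of class `"read_counts"`.
#' @export
read_count_matrix <- function(binmap, counts) {
  counts <- as.matrix(counts)
  assert_that(nrow(counts) == nrow(binmap),
              "count matrix must have one row per bin")
  assert_that(all(counts >= 0) && !anyNA(counts),
              "counts must be complete and >= 0")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell_%03d", seq_len(ncol(counts)))
  structure(list(binmap = binmap, counts = counts,
                 cell_ids = colnames(counts)),
            class = "read_counts")
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf("ReadCountMatrix: %d bins x %d cells, mean count %.2f\n",
              nrow(x$counts), ncol(x$counts), mean(x$counts)))
  invisible(x)
}

#' Read-depth simulation configuration
#'
#' @param mean_reads_per_bin_per_copy expected reads in a reference-width bin
#'   per chromosome copy (the library-depth QC in [call_and_curate()] is
#'   anchored at 5).
#' @param dispersion negative-binomial overdispersion (var = mu + d * mu^2);
#'   0 gives Poisson counts.
#' @param gc_bias_amplitude strength `a` of the multiplicative quadratic GC
#'   bias `max(0, 1 + a * (gc - 0.45)^2)` centred at GC 0.45; negative values
#'   depress coverage away from mid-GC. 0 disables the bias.
#' @param seed RNG seed.
#' @return A list of class `"read_sim_config"`.
#' @export
read_sim_config <- function(mean_reads_per_bin_per_copy = 5,
                            dispersion = 0,
                            gc_bias_amplitude = 0,
                            seed = 1L) {
  assert_that(mean_reads_per_bin_per_copy > 0,
              "mean_reads_per_bin_per_copy must be > 0")
  assert_that(dispersion >= 0, "dispersion must be >= 0")
  structure(list(mean_reads_per_bin_per_copy = mean_reads_per_bin_per_copy,
                 dispersion = dispersion,
                 gc_bias_amplitude = gc_bias_amplitude,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

gc_bias_factor <- function(gc, amplitude) {
  f <- 1 + amplitude * (gc - 0.45)^2
  f[is.na(gc)] <- 1
  pmax(f, 0)
}

#' Simulate binned read counts for a cell population
#'
#' The expected count for (cell, bin) is
#' `copy * mean_reads_per_bin_per_copy * gc_factor(bin) * width / avg_width`,
#' drawn negative-binomially with the configured dispersion (Poisson at 0).
#' Copy-0 bins always yield count 0.
#'
#' @param population a [cell_population()].
#' @param config a [read_sim_config()].
#' @return A [read_count_matrix()] on the population's bin map.
#' @export
simulate_read_counts <- function(population, config) {
  stopifnot(inherits(population, "cell_population"),
            inherits(config, "read_sim_config"))
  profiles <- population$profiles
  assert_that(all(profiles >= 0), "copy states must be >= 0")
  binmap <- population$binmap
  per_bin <- config$mean_reads_per_bin_per_copy *
    gc_bias_factor(binmap$gc, config$gc_bias_amplitude) *
    bin_widths(binmap) / attr(binmap, "avg_width")
  mu <- profiles * per_bin  # recycled column-wise: bins x cells
  with_seed(config$seed, {
    counts <- matrix(rnbinom_md(length(mu), as.vector(mu), config$dispersion),
                     nrow(mu), ncol(mu))
    colnames(counts) <- colnames(profiles)
    read_count_matrix(binmap, counts)
  })
}
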