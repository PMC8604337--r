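# Shared fixtures and independent brute-force oracles.

tiny_genome <- function() c(chr1 = 30e6, chr2 = 20e6)

human_autosomes <- function() {
  stats::setNames(
    c(249, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
      114, 107, 102, 90, 83, 80, 59, 64, 47, 51) * 1e6,
    paste0("chr", 1:22))
}

# a bin map with explicit widths on one or more chromosomes
manual_binmap <- function(widths_mb, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("chr1", length(widths_mb))
  starts <- unlist(lapply(split(widths_mb, factor(chrom, levels = unique(chrom))),
                          function(w) cumsum(c(0, w[-length(w)]))))
  ends <- unlist(lapply(split(widths_mb, factor(chrom, levels = unique(chrom))),
                        function(w) cumsum(w)))
  bin_map(chrom = chrom[order(factor(chrom, levels = unique(chrom)))],
          start = starts * 1e6, end = ends * 1e6)
}

random_small_population <- function(max_cells = 5, max_bins = 12) {
  n_cells <- sample(2:max_cells, 1)
  n_bins <- sample(2:max_bins, 1)
  n_chrom <- sample(1:2, 1)
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n_bins, replace = TRUE))
  widths <- sample(1:5, n_bins, replace = TRUE)
  bm <- manual_binmap(widths, chrom)
  profiles <- matrix(sample(0:4, n_bins * n_cells, replace = TRUE),
                     n_bins, n_cells)
  cell_population(bm, profiles)
}

# Brute-force score oracles: explicit loops over bins and cell pairs,
# independent of the package's vectorized implementations.
brute_aneuploidy <- function(pop, euploid = 2) {
  w <- pop$binmap$end - pop$binmap$start
  cells <- numeric(ncol(pop$profiles))
  for (j in seq_along(cells)) {
    num <- 0
    for (b in seq_len(nrow(pop$binmap)))
      num <- num + w[b] * abs(pop$profiles[b, j] - euploid)
    cells[j] <- num / sum(w)
  }
  mean(cells)
}

brute_heterogeneity <- function(pop) {
  w <- pop$binmap$end - pop$binmap$start
  n <- ncol(pop$profiles)
  num <- 0
  for (b in seq_len(nrow(pop$binmap))) {
    unequal <- 0; pairs <- 0
    for (c1 in seq_len(n - 1)) for (c2 in (c1 + 1):n) {
      pairs <- pairs + 1
      if (pop$profiles[b, c1] != pop$profiles[b, c2]) unequal <- unequal + 1
    }
    num <- num + w[b] * unequal / pairs
  }
  num / sum(w)
}

brute_structural <- function(pop) {
  genome_mb <- sum(pop$binmap$end - pop$binmap$start) / 1e6
  cells <- numeric(ncol(pop$profiles))
  for (j in seq_along(cells)) {
    k <- 0
    for (b in 2:nrow(pop$binmap)) {
      if (pop$binmap$chrom[b] == pop$binmap$chrom[b - 1] &&
          pop$profiles[b, j] != pop$profiles[b - 1, j]) k <- k + 1
    }
    cells[j] <- k / genome_mb
  }
  mean(cells)
}

# Brute-force best-segment oracles (exhaustive enumeration, <= ~30 bins)
brute_best_t <- function(x, minlen = 2) {
  n <- length(x)
  best <- list(stat = 0, i = NA, j = NA)
  for (i in 1:n) for (j in i:n) {
    m <- j - i + 1; mm <- n - m
    left <- i - 1; right <- n - j
    if (m < minlen || mm < minlen) next
    if (left != 0 && left < minlen) next
    if (right != 0 && right < minlen) next
    inside <- x[i:j]; outside <- x[-(i:j)]
    ssw <- sum((inside - mean(inside))^2) + sum((outside - mean(outside))^2)
    varp <- max(ssw / (n - 2), 1e-24)
    stat <- abs(mean(inside) - mean(outside)) / sqrt(varp * (1 / m + 1 / mm))
    if (stat > best$stat) best <- list(stat = stat, i = i, j = j)
  }
  best
}

brute_best_energy <- function(x, minlen = 2) {
  n <- length(x)
  energy <- function(a, b) {
    m <- length(a); mm <- length(b)
    cross <- mean(outer(a, b, function(p, q) abs(p - q)))
    wa <- mean(outer(a, a, function(p, q) abs(p - q)))
    wb <- mean(outer(b, b, function(p, q) abs(p - q)))
    m * mm / (m + mm) * (2 * cross - wa - wb)
  }
  best <- list(stat = 0, i = NA, j = NA)
  for (i in 1:n) for (j in i:n) {
    m <- j - i + 1; mm <- n - m
    left <- i - 1; right <- n - j
    if (m < minlen || mm < minlen) next
    if (left != 0 && left < minlen) next
    if (right != 0 && right < minlen) next
    stat <- energy(x[i:j], x[-(i:j)])
    if (stat > best$stat) best <- list(stat = stat, i = i, j = j)
  }
  best
}
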