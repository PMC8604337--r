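test_that("gc correction is the identity for uniform GC and drops blacklisted bins", {
  bm <- manual_binmap(rep(1, 20))
  bm$gc <- 0.45
  bm$blacklisted[3] <- TRUE
  counts <- read_count_matrix(bm, matrix(rpois(40, 20), 20, 2))
  corr <- gc_correct(counts)
  expect_equal(nrow(corr$binmap), 19)
  expect_false(any(corr$binmap$blacklisted))
  expect_equal(corr$counts, counts$counts[-3, ], ignore_attr = TRUE)

  bm$blacklisted[] <- TRUE
  all_bl <- read_count_matrix(bm, matrix(1, 20, 2))
  expect_error(gc_correct(all_bl), "blacklisted")
})

test_that("gc correction removes a quadratic GC bias", {
  set.seed(21)
  n <- 3000
  bm <- manual_binmap(rep(1, n))
  bm$gc <- rbeta(n, 50, 60)
  pop <- cell_population(bm, matrix(2L, n, 1))
  counts <- simulate_read_counts(
    pop, read_sim_config(50, dispersion = 0.02, gc_bias_amplitude = -8, seed = 22))
  # bias is present before correction ...
  fit_raw <- summary(lm(counts$counts[, 1] ~ poly(bm$gc, 2)))
  expect_gt(max(abs(fit_raw$coefficients[2:3, "t value"])), 2)
  # ... and gone afterwards (|t| < 2 for the linear term on 3,000 bins)
  corr <- gc_correct(counts)
  fit <- summary(lm(corr$counts[, 1] ~ corr$binmap$gc))
  expect_lt(abs(fit$coefficients[2, "t value"]), 2)
})

test_that("both segmenters recover a noiseless step at the exact boundary", {
  x <- c(rep(5, 10), rep(15, 10))
  p <- caller_params(seed = 23)
  expect_equal(segment_binary(x, p), 10)
  expect_equal(segment_edivisive(x, p), 10)
  # constant tracks yield no change points
  expect_length(segment_binary(rep(4, 30), p), 0)
  expect_length(segment_edivisive(rep(4, 30), p), 0)
})

test_that("best-segment statistics match brute-force enumeration", {
  set.seed(24)
  for (rep in 1:5) {
    x <- rnorm(25, 10, 2)
    x[8:14] <- x[8:14] + rnorm(7, 6, 1)
    for (method in c("t", "energy")) {
      got <- CINspect:::cpp_best_segment(x, 2L, method)
      want <- if (method == "t") brute_best_t(x) else brute_best_energy(x)
      expect_equal(got$stat, want$stat, tolerance = 1e-10)
      expect_equal(c(got$i, got$j), c(want$i, want$j))
    }
  }
})

test_that("segmentation is invariant to adding a constant and respects chromosomes", {
  set.seed(25)
  x <- c(rnorm(20, 10), rnorm(15, 25), rnorm(20, 10))
  p <- caller_params(seed = 26)
  expect_equal(segment_binary(x, p), segment_binary(x + 1000, p))
  expect_equal(segment_edivisive(x, p), segment_edivisive(x + 1000, p))
  # a sharp boundary between chromosomes is not a change point
  y <- c(rep(10, 20), rep(30, 20))
  chrom <- rep(c("chr1", "chr2"), each = 20)
  expect_length(segment_binary(y, p, chrom), 0)
  expect_length(segment_edivisive(y, p, chrom), 0)
  # seeded permutation tests reproduce exactly
  expect_identical(segment_edivisive(x, p), segment_edivisive(x, p))
})

test_that("copy-number assignment integerizes segment means at the right scale", {
  # three noiseless segments at means 10/20/30: scale 10, copies 1/2/3
  track <- rep(c(10, 20, 30), each = 10)
  prof <- assign_copy_numbers(track, c(10, 20), caller_params())
  expect_equal(as.integer(prof), rep(c(1L, 2L, 3L), each = 10),
               ignore_attr = TRUE)
  expect_equal(attr(prof, "scale"), 10)
  # all-zero tracks give all-zero profiles
  z <- assign_copy_numbers(rep(0, 12), integer(), caller_params())
  expect_true(all(z == 0))
  # a constant diploid-like track lands on copy 2 via the euploid tie-break
  d <- assign_copy_numbers(rep(42, 20), integer(), caller_params())
  expect_true(all(d == 2))
  expect_equal(attr(d, "scale"), 21)
})

test_that("concordance counts agreeing bins and is symmetric", {
  a <- rep(2L, 10); b <- a; b[4] <- 3L
  expect_equal(concordance(a, a), 1)
  expect_equal(concordance(a, b), 0.9)
  expect_equal(concordance(b, a), concordance(a, b))
  expect_error(concordance(a, b[-1]), "different bin maps")
  # blacklisted bins are excluded
  expect_equal(concordance(a, b, blacklisted = c(rep(FALSE, 3), TRUE, rep(FALSE, 6))), 1)
})

test_that("curation applies the exact threshold boundaries", {
  p <- caller_params()
  # mean reads per bin per copy: exactly 5 passes, 4.9 fails
  expect_true(CINspect:::curation_decision(1, 5, p)$pass)
  d <- CINspect:::curation_decision(1, 4.9, p)
  expect_false(d$pass); expect_equal(d$reason, "low-coverage")
  # concordance: exactly 0.90 passes, 0.899 fails
  expect_true(CINspect:::curation_decision(0.90, 10, p)$pass)
  d <- CINspect:::curation_decision(0.899, 10, p)
  expect_false(d$pass); expect_equal(d$reason, "low-concordance")
})

test_that("call_and_curate keeps a noiseless diploid cell at exactly 5 reads/bin/copy", {
  bm <- manual_binmap(rep(1, 40), rep(c("chr1", "chr2"), each = 20))
  bm$gc <- 0.45
  mk <- function(v) read_count_matrix(bm, matrix(v, 40, 1))
  p <- caller_params(seed = 27)
  res5 <- call_and_curate(mk(10), params = p)
  expect_true(res5$qc$pass)
  expect_equal(res5$qc$concordance, 1)
  expect_equal(res5$qc$mean_reads_per_bin_per_copy, 5)
  expect_true(all(res5$population$profiles == 2))
  # 4.9 reads/bin/copy is discarded as low coverage
  expect_warning(res49 <- call_and_curate(mk(9.8), params = p), "no cell passed")
  expect_false(res49$qc$pass)
  expect_equal(res49$qc$reason, "low-coverage")
  expect_equal(res49$qc$mean_reads_per_bin_per_copy, 4.9)
})

test_that("call_and_curate recovers simulated profiles end to end", {
  # a near-diploid population: the euploid-reference tie-break assumes most
  # of the genome sits at copy 2, so the toy genome needs several chromosomes
  cfg <- population_sim_config(6, c(chr1 = 60e6, chr2 = 50e6, chr3 = 45e6,
                                    chr4 = 40e6),
                               bin_width = 1e6,
                               founder_event_count = 1, missegregation_rate = 0.3,
                               segmental_rate = 0.3, seed = 28)
  pop <- simulate_population(cfg)
  counts <- simulate_read_counts(pop, read_sim_config(30, dispersion = 0.05, seed = 29))
  res <- call_and_curate(counts, params = caller_params(seed = 30))
  expect_true(all(res$qc$pass))
  expect_gt(mean(res$population$profiles == pop$profiles), 0.95)
})
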