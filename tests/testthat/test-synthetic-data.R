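test_that("no-event configurations give constant euploid populations", {
  cfg <- population_sim_config(5, tiny_genome(), bin_width = 1e6, seed = 1)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$binmap), 50)
  expect_true(all(pop$profiles == 2))
  sc <- score_sample(pop)
  expect_equal(sc$aneuploidy, 0)
  expect_equal(sc$heterogeneity, 0)
  expect_equal(sc$structural, 0)
})

test_that("population simulation is a pure function of config and seed", {
  cfg <- population_sim_config(8, tiny_genome(), bin_width = 1e6,
                               founder_event_count = 3, wgd_probability = 0.5,
                               missegregation_rate = 1, segmental_rate = 1,
                               seed = 11)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$binmap, b$binmap)
  # and the global RNG stream is left untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_population(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("certain whole-genome duplication doubles the base ploidy", {
  cfg <- population_sim_config(4, tiny_genome(), bin_width = 1e6,
                               wgd_probability = 1, seed = 2)
  expect_true(all(simulate_population(cfg)$profiles == 4))
})

test_that("population config rejects invalid inputs", {
  expect_error(population_sim_config(0, tiny_genome()), "n_cells")
  expect_error(population_sim_config(5, numeric()), "non-empty")
  expect_error(population_sim_config(5, tiny_genome(), bin_width = 0),
               "bin_width")
  expect_error(population_sim_config(5, tiny_genome(), wgd_probability = 1.5),
               "wgd_probability")
  expect_error(
    population_sim_config(5, tiny_genome(), subclone_fractions = list(
      list(fraction = 0.7, events = NULL), list(fraction = 0.5, events = NULL))),
    "fractions")
})

test_that("subclone fractions carve out founder-sharing subpopulations", {
  ev <- data.frame(chrom = "chr2", start = NA, end = NA, delta = 1L)
  cfg <- population_sim_config(10, tiny_genome(), bin_width = 1e6,
                               subclone_fractions = list(
                                 list(fraction = 0.3, events = ev)),
                               seed = 3)
  pop <- simulate_population(cfg)
  expect_equal(sum(pop$clone == "subclone_1"), 3)
  sub <- pop$profiles[, pop$clone == "subclone_1"]
  expect_true(all(sub[pop$binmap$chrom == "chr2", ] == 3))
  expect_true(all(sub[pop$binmap$chrom == "chr1", ] == 2))
  expect_true(all(pop$profiles[, pop$clone == "founder"] == 2))
})

test_that("read counts follow the copy-proportional mean model", {
  cfg <- population_sim_config(1, c(chrA = 10e6), bin_width = 1e6, seed = 4)
  pop <- simulate_population(cfg)
  pop$profiles[, 1] <- 3L
  # 10,000 effective draws of a copy-3 bin at 5 reads/bin/copy: mean 15
  big <- cell_population(pop$binmap, matrix(3L, 10, 1000))
  counts <- simulate_read_counts(big, read_sim_config(5, seed = 5))
  expect_lt(abs(mean(counts$counts) - 15), 3 * sd(counts$counts) / 100)

  # copy-0 bins always yield zero counts
  pop$profiles[, 1] <- 0L
  z <- simulate_read_counts(pop, read_sim_config(5, dispersion = 0.3, seed = 6))
  expect_true(all(z$counts == 0))

  # seeded determinism
  c1 <- simulate_read_counts(big, read_sim_config(5, dispersion = 0.1, seed = 7))
  c2 <- simulate_read_counts(big, read_sim_config(5, dispersion = 0.1, seed = 7))
  expect_identical(c1$counts, c2$counts)
})

test_that("spectral-count simulation emits design-faithful tables", {
  cfg <- spectra_sim_config(seed = 8)
  sim <- simulate_spectral_counts(cfg)
  expect_s3_class(sim$table, "spectral_counts")
  expect_setequal(unique(sim$table$condition), c("EV", "WT", "K27M"))
  # anchor present in every replicate
  h4 <- sim$table[sim$table$protein == "H4", ]
  expect_equal(nrow(h4), 12)
  # bait-specific proteins never appear in EV
  ev_prots <- unique(sim$table$protein[sim$table$condition == "EV"])
  expect_false(any(grepl("^(WTSP|KMSP|SHARED)", ev_prots)))
  # determinism
  sim2 <- simulate_spectral_counts(cfg)
  expect_identical(sim$table, sim2$table)
  expect_error(spectra_sim_config(n_replicates_per_condition = 0), "replicate")
})

test_that("null spectra (zero effect) leave bait conditions at background level", {
  cfg <- spectra_sim_config(n_background_proteins = 200, n_wt_specific = 0,
                            n_k27m_specific = 0, n_shared = 0,
                            effect_mean = 0, background_mean = 4, seed = 9)
  sim <- simulate_spectral_counts(cfg)
  means <- tapply(sim$table$spec_count[sim$table$protein != "H4"],
                  sim$table$condition[sim$table$protein != "H4"], mean)
  expect_lt(max(means) - min(means), 0.5)
})

test_that("CNA burden simulation respects group structure and seed", {
  cfg <- burden_sim_config(c(A = 10, B = 20), c(A = 8, B = 3), seed = 10)
  df <- simulate_cna_burden(cfg)
  expect_equal(as.vector(table(df$subtype)[c("A", "B")]), c(10, 20))
  expect_true(all(df$total >= 0))
  expect_identical(df, simulate_cna_burden(cfg))
  expect_error(burden_sim_config(c(A = 1, B = 5), c(A = 1, B = 1)), "at least 2")
  expect_error(burden_sim_config(c(A = 5), c(B = 1)), "same groups")
})
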