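make_table <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(protein = r[[1]], condition = r[[2]],
               replicate = as.integer(r[[3]]), spec_count = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)))
  spectral_count_table(df)
}

test_that("replicate QC keeps bait replicates with anchor above EV background", {
  tab <- make_table(list(
    list("H4", "EV", 1, 2), list("H4", "EV", 2, 2),
    list("H4", "WT", 1, 10), list("P1", "WT", 1, 5),
    list("H4", "WT", 2, 1), list("P1", "WT", 2, 99),
    list("H4", "K27M", 1, 7), list("P1", "K27M", 1, 3)))
  kept <- replicate_qc(tab)
  expect_false(any(kept$condition == "WT" & kept$replicate == 2))
  expect_true(any(kept$condition == "WT" & kept$replicate == 1))
  expect_true(all(tab[tab$condition == "EV", "replicate"] %in% kept$replicate[kept$condition == "EV"]))

  # anchor counts equal to background are "not above": all bait replicates drop
  flat <- make_table(list(
    list("H4", "EV", 1, 10), list("H4", "WT", 1, 10), list("H4", "K27M", 1, 10)))
  expect_error(replicate_qc(flat), "above background")
  # missing EV anchor is a precondition error
  noev <- make_table(list(
    list("P1", "EV", 1, 3), list("H4", "WT", 1, 5), list("H4", "K27M", 1, 5)))
  expect_error(replicate_qc(noev), "anchor")
})

test_that("condition means zero-fill proteins missing from a replicate", {
  tab <- make_table(list(
    list("H4", "EV", 1, 5), list("H4", "EV", 2, 5),
    list("H4", "WT", 1, 20), list("H4", "WT", 2, 20),
    list("H4", "WT", 3, 20), list("H4", "WT", 4, 20),
    list("P1", "WT", 1, 6), list("P1", "WT", 3, 6),
    list("H4", "K27M", 1, 20)))
  m <- condition_means(tab)
  expect_equal(m$WT[m$protein == "P1"], 3)   # seen in 2 of 4 replicates at 6
  expect_equal(m$WT[m$protein == "H4"], 20)
  expect_equal(m$K27M[m$protein == "H4"], 20)  # single replicate
  expect_equal(m$EV[m$protein == "P1"], 0)
})

test_that("background subtraction clamps at zero and flags background-only proteins", {
  means <- data.frame(protein = c("A", "B", "C"),
                      EV = c(0, 3, 1), WT = c(4, 2, 5), K27M = c(4, 1, 1))
  out <- subtract_background(means)
  expect_equal(out$means$WT[out$means$protein == "A"], 4)    # EV 0: identity
  expect_equal(out$background_only, "B")                     # both clamp to 0
  expect_equal(out$means$WT[out$means$protein == "C"], 4)
  expect_equal(out$means$K27M[out$means$protein == "C"], 0)
})

test_that("anchor normalization rescales K27M to the WT pull-down yield", {
  tab <- make_table(list(
    list("H4", "EV", 1, 1), list("P1", "EV", 1, 1),
    list("H4", "WT", 1, 40), list("P1", "WT", 1, 7),
    list("H4", "K27M", 1, 20), list("P1", "K27M", 1, 5)))
  corrected <- subtract_background(condition_means(tab))
  corrected$means <- corrected$means[corrected$means$protein != "H4", ]
  norm <- normalize_to_anchor(corrected, tab)
  expect_equal(attr(norm, "anchor_factors")[["WT"]], 1)
  expect_equal(attr(norm, "anchor_factors")[["K27M"]], 2)
  expect_equal(norm$means$K27M[norm$means$protein == "P1"], (5 - 1) * 2)
  # zero anchor in a bait condition is an error
  tab0 <- make_table(list(
    list("H4", "EV", 1, 1), list("H4", "WT", 1, 40),
    list("H4", "K27M", 1, 0), list("P1", "K27M", 1, 5)))
  expect_error(normalize_to_anchor(corrected, tab0), "> 0")
})

test_that("classification applies presence and enrichment-delta boundaries", {
  mk <- function(wt, km) list(means = data.frame(protein = "P", WT = wt, K27M = km))
  lab <- function(wt, km) classify_interactors(mk(wt, km))$proteins$label
  expect_equal(lab(5, 5), "common-not-enriched")
  expect_equal(lab(10, 3), "WT-enriched")       # difference 7 > 2
  expect_equal(lab(4, 6), "common-not-enriched") # |diff| = 2 is the boundary
  expect_equal(lab(0, 4), "K27M-unique")
  expect_equal(lab(4, 0), "WT-unique")
  expect_equal(lab(3, 10), "K27M-enriched")
})

test_that("pipeline satisfies the Venn identity and label-swap symmetry", {
  sim <- simulate_spectral_counts(spectra_sim_config(seed = 41))
  cls <- run_interactome_pipeline(sim$table)
  v <- cls$venn
  expect_equal(v[["common_total"]],
               v[["common_not_enriched"]] + v[["enriched_WT"]] + v[["enriched_K27M"]])
  expect_equal(sum(v[c("unique_WT", "unique_K27M", "common_total",
                       "background_only")]),
               length(unique(sim$table$protein)) - 1)  # all but the anchor

  # swapping WT and K27M labels (with symmetric anchor levels) swaps the venn
  cfgs <- spectra_sim_config(h4_mean_per_condition = c(EV = 10, WT = 40, K27M = 40),
                             seed = 42)
  sym <- simulate_spectral_counts(cfgs)
  swapped <- sym$table
  swapped$condition <- c(EV = "EV", WT = "K27M", K27M = "WT")[swapped$condition]
  swapped <- spectral_count_table(swapped)
  a <- run_interactome_pipeline(sym$table)$venn
  b <- run_interactome_pipeline(swapped)$venn
  expect_equal(a[["unique_WT"]], b[["unique_K27M"]])
  expect_equal(a[["unique_K27M"]], b[["unique_WT"]])
  expect_equal(a[["enriched_WT"]], b[["enriched_K27M"]])
  expect_equal(a[["common_not_enriched"]], b[["common_not_enriched"]])
})

test_that("doubling one condition's counts (anchor included) cancels for EV-absent proteins", {
  tab <- make_table(list(
    list("H4", "EV", 1, 2),
    list("H4", "WT", 1, 40), list("P1", "WT", 1, 7),
    list("H4", "K27M", 1, 20), list("P1", "K27M", 1, 6)))
  doubled <- tab
  sel <- doubled$condition == "K27M"
  doubled$spec_count[sel] <- doubled$spec_count[sel] * 2
  doubled <- spectral_count_table(doubled)
  a <- run_interactome_pipeline(tab)
  b <- run_interactome_pipeline(doubled)
  expect_equal(b$proteins$K27M[b$proteins$protein == "P1"],
               a$proteins$K27M[a$proteins$protein == "P1"])
})

test_that("a table with equal conditions yields no unique or enriched calls", {
  rows <- list(list("H4", "EV", 1, 2))
  for (cond in c("WT", "K27M")) {
    rows <- c(rows, list(list("H4", cond, 1, 10)))
    for (p in paste0("P", 1:6)) rows <- c(rows, list(list(p, cond, 1, 7)))
  }
  cls <- run_interactome_pipeline(make_table(rows))
  expect_equal(cls$venn[["unique_WT"]] + cls$venn[["unique_K27M"]], 0)
  expect_equal(cls$venn[["enriched_WT"]] + cls$venn[["enriched_K27M"]], 0)
  expect_equal(cls$venn[["common_not_enriched"]], 6)
})

test_that("designed interactor classes are recovered by the full pipeline", {
  hits <- 0; total <- 0
  for (s in 1:20) {
    sim <- simulate_spectral_counts(spectra_sim_config(seed = 500 + s))
    cls <- run_interactome_pipeline(sim$table)
    m <- merge(cls$proteins, sim$truth)
    interactors <- m[m$truth != "background-only", ]
    ok <- ifelse(interactors$truth == "common",
                 interactors$label %in% c("common-not-enriched", "WT-enriched",
                                          "K27M-enriched"),
                 interactors$label == interactors$truth)
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gt(hits / total, 0.95)
})
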