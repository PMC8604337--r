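#' Sum autosomal CNA burden per tumor
#'
#' Accepts either per-chromosome event tables (columns `tumor`, `subtype`,
#' `chromosome`, `count`) or pre-summed tables (columns `tumor`, `subtype`,
#' `total`), which pass through unchanged. Sex chromosomes (X/Y) and the
#' mitochondrial contig (M/MT) are excluded from the sums; any other
#' unrecognizable chromosome label is an error naming the offending value.
#'
#' @param table data.frame in one of the two layouts above.
#' @return Data.frame of class `"cna_burden"` with columns `tumor`,
#'   `subtype`, `total`.
#' @export
sum_autosomal_burden <- function(table) {
  if (all(c("tumor", "subtype", "total") %in% names(table))) {
    out <- as.data.frame(table)[, c("tumor", "subtype", "total")]
    class(out) <- c("cna_burden", "data.frame")
    return(out)
  }
  need <- c("tumor", "subtype", "chromosome", "count")
  assert_that(all(need %in% names(table)),
              "table needs columns tumor/subtype/chromosome/count (or a pre-summed total)")
  assert_that(all(table$count >= 0), "event counts must be >= 0")
  chrom <- toupper(sub("^CHR", "", toupper(as.character(table$chromosome))))
  autosome <- chrom %in% as.character(1:22)
  sexmito <- chrom %in% c("X", "Y", "M", "MT")
  bad <- !(autosome | sexmito)
  if (any(bad))
    stop("unknown chromosome label(s): ",
         paste(unique(table$chromosome[bad]), collapse = ", "), call. = FALSE)
  auto <- table[autosome, , drop = FALSE]
  tumors <- unique(table[, c("tumor", "subtype")])
  totals <- tapply(auto$count, factor(auto$tumor, levels = tumors$tumor), sum)
  totals[is.na(totals)] <- 0
  out <- data.frame(tumor = tumors$tumor, subtype = tumors$subtype,
                    total = as.vector(totals), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cna_burden", "data.frame")
  out
}

#' Mann-Whitney U test (rank-sum) for two groups
#'
#' U is computed from joint mid-ranks (`U = R_a - n_a(n_a+1)/2`). The
#' two-sided p-value is exact — full enumeration of the permutation null —
#' when `n_a + n_b <= 12` and the pooled values contain no ties; otherwise a
#' normal approximation with tie correction and continuity correction is
#' used. Two-sided p = min(1, 2 * one-sided).
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @param exact_max largest pooled sample size for the exact enumeration
#'   path (default 12).
#' @return A list of class `"group_comparison"`: `n_a`, `n_b`, `U` (for
#'   `group_a`), `p_value`, `method` (`"exact"` or
#'   `"normal-approximation"`).
#' @export
mann_whitney <- function(group_a, group_b, exact_max = 12L) {
  n_a <- length(group_a); n_b <- length(group_b)
  assert_that(n_a >= 1 && n_b >= 1, "both groups must be non-empty")
  pooled <- c(group_a, group_b)
  assert_that(!anyNA(pooled), "values must not contain NA")
  r <- rank(pooled)  # mid-ranks
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0

  if (!has_ties && n_a + n_b <= exact_max) {
    # exact: U is distribution-free, enumerate all C(n, n_a) group labelings
    n <- n_a + n_b
    combs <- combn(n, n_a)
    ranks_all <- seq_len(n)  # no ties: ranks are a permutation of 1..n
    u_null <- colSums(matrix(ranks_all[combs], nrow = n_a)) -
      n_a * (n_a + 1) / 2
    one_sided <- min(mean(u_null <= U), mean(u_null >= U))
    p <- min(1, 2 * one_sided)
    method <- "exact"
  } else {
    n <- n_a + n_b
    mu <- n_a * n_b / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- sign(U - mu) * max(0, abs(U - mu) - 0.5) / sqrt(sigma2)  # continuity-corrected
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  structure(list(n_a = n_a, n_b = n_b, U = U, p_value = p, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney: n = %d vs %d, U = %.1f, two-sided p = %.4g (%s)\n",
              x$n_a, x$n_b, x$U, x$p_value, x$method))
  invisible(x)
}

#' Pairwise CNA-burden comparisons between subtypes
#'
#' Runs [mann_whitney()] on every pair of subtype groups in a summed burden
#' table (raw p-values; optional Bonferroni correction over the pairs).
#'
#' @param burden a `"cna_burden"` data.frame (see [sum_autosomal_burden()]).
#' @param bonferroni also report Bonferroni-adjusted p-values (default
#'   FALSE; raw p is always reported).
#' @return Data.frame with one row per subtype pair: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `U`, `p_value`, `method` (and `p_bonferroni` if
#'   requested).
#' @export
compare_burden_groups <- function(burden, bonferroni = FALSE) {
  assert_that(all(c("subtype", "total") %in% names(burden)),
              "burden table needs subtype and total columns")
  groups <- unique(burden$subtype)
  assert_that(length(groups) >= 2, "need at least two subtype groups")
  pairs <- combn(groups, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- burden$total[burden$subtype == pairs[1, i]]
    b <- burden$total[burden$subtype == pairs[2, i]]
    mw <- mann_whitney(a, b)
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               n_a = mw$n_a, n_b = mw$n_b, U = mw$U, p_value = mw$p_value,
               method = mw$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni)
    out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}
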