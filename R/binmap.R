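#' Genome bin maps
#'
#' A bin map is the coordinate frame for all single-cell copy-number work: an
#' ordered set of genomic bins, each with a chromosome, 0-based half-open
#' coordinates, a GC fraction and a blacklist flag. Bins are sorted by
#' (chromosome, start) and never span two chromosomes; overlapping (sliding)
#' bins are permitted.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open coordinates in bp.
#' @param gc GC fraction per bin in \[0, 1\] (NA allowed).
#' @param blacklisted logical flag per bin marking artefact-prone regions.
#' @param avg_width declared average bin width in bp (metadata).
#' @param step declared step size in bp (metadata; equals `avg_width` for
#'   non-overlapping bins).
#'
#' @return A `data.frame` of class `"binmap"` with columns `chrom`, `start`,
#'   `end`, `gc`, `blacklisted`, sorted by (chromosome, start).
#' @export
bin_map <- function(chrom, start, end, gc = NA_real_, blacklisted = FALSE,
                    avg_width = NULL, step = NULL) {
  assert_that(length(chrom) >= 1L, "bin map must contain at least one bin")
  bm <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    gc = rep_len(as.numeric(gc), length(chrom)),
    blacklisted = rep_len(as.logical(blacklisted), length(chrom)),
    stringsAsFactors = FALSE
  )
  assert_that(all(bm$end > bm$start), "every bin must satisfy end > start")
  bad_gc <- !is.na(bm$gc) & (bm$gc < 0 | bm$gc > 1)
  assert_that(!any(bad_gc), "gc fractions must lie in [0, 1]")
  ord <- order(bm$chrom, bm$start, bm$end)
  bm <- bm[ord, , drop = FALSE]
  rownames(bm) <- NULL
  attr(bm, "avg_width") <- avg_width %||% mean(bm$end - bm$start)
  attr(bm, "step") <- step %||% attr(bm, "avg_width")
  class(bm) <- c("binmap", "data.frame")
  bm
}

#' Tile chromosomes into fixed-width bins
#'
#' Builds a non-overlapping bin map covering each chromosome with `bin_width`
#' bins; the final bin of a chromosome is truncated at the chromosome end.
#'
#' @param chromosome_lengths named numeric vector, chromosome name -> length
#'   in bp.
#' @param bin_width bin width in bp (> 0).
#' @param gc optional GC fraction per bin (recycled); defaults to NA.
#' @return A [bin_map()].
#' @export
make_bins <- function(chromosome_lengths, bin_width, gc = NA_real_) {
  assert_that(length(chromosome_lengths) >= 1L && all(chromosome_lengths > 0),
              "chromosome_lengths must be a non-empty vector of positive lengths")
  assert_that(is.numeric(bin_width) && bin_width > 0, "bin_width must be > 0")
  assert_that(!is.null(names(chromosome_lengths)) &&
                !anyDuplicated(names(chromosome_lengths)),
              "chromosome_lengths must have unique names")
  pieces <- lapply(names(chromosome_lengths), function(ch) {
    len <- chromosome_lengths[[ch]]
    starts <- seq(0, len - 1, by = bin_width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_width, len),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  bin_map(df$chrom, df$start, df$end, gc = gc,
          avg_width = bin_width, step = bin_width)
}

bin_widths <- function(binmap) binmap$end - binmap$start

bin_keys <- function(binmap) {
  sprintf("%s:%d-%d", binmap$chrom, as.integer(binmap$start),
          as.integer(binmap$end))
}

#' @export
print.binmap <- function(x, ...) {
  cat(sprintf("GenomeBinMap: %d bins on %d chromosome(s), avg width %.0f bp, %d blacklisted\n",
              nrow(x), length(unique(x$chrom)), attr(x, "avg_width"),
              sum(x$blacklisted)))
  print(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

same_binmap <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
    all(a$start == b$start) && all(a$end == b$end)
}
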