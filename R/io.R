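#' Read a genome bin map from BED
#'
#' Expects at least 3 tab-separated columns (chrom, start, end; 0-based
#' half-open), optionally followed by name, gc and blacklist (0/1) columns.
#' Input is sorted on load (with a warning when it was unsorted); malformed
#' intervals are reported with their line numbers.
#'
#' @param path BED file path.
#' @return A [bin_map()].
#' @export
read_binmap <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 3, "BED input needs at least 3 columns")
  bad <- which(!(is.numeric(df[[2]]) & is.numeric(df[[3]])) |
                 df[[3]] <= df[[2]])
  if (length(bad))
    stop("malformed BED interval (end <= start) at line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  gc <- if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else NA_real_
  bl <- if (ncol(df) >= 6) df[[6]] != 0 else FALSE
  unsorted <- is.unsorted(order(df[[1]], df[[2]])) ||
    any(order(df[[1]], df[[2]], df[[3]]) != seq_len(nrow(df)))
  if (unsorted) warning("bin map was not sorted; sorting on load")
  bin_map(df[[1]], df[[2]], df[[3]], gc = gc, blacklisted = bl)
}

#' Write a genome bin map as BED
#'
#' Columns: chrom, start, end, name (`bin_<i>`), gc, blacklist (0/1).
#'
#' @param binmap a [bin_map()].
#' @param path output path.
#' @export
write_binmap <- function(binmap, path) {
  df <- data.frame(binmap$chrom, as.integer(binmap$start),
                   as.integer(binmap$end),
                   sprintf("bin_%d", seq_len(nrow(binmap))),
                   ifelse(is.na(binmap$gc), ".", format(binmap$gc)),
                   as.integer(binmap$blacklisted))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write bin-by-cell matrices as TSV
#'
#' Layout: header row of cell IDs; first column `bin` holds the
#' `chrom:start-end` key in bin-map order. Writing then reading reproduces
#' the values exactly; integer matrices (copy-number profiles) are written
#' without decimal points.
#'
#' @param path TSV path.
#' @param binmap the [bin_map()] the matrix is bound to.
#' @return `read_matrix`: a [read_count_matrix()] when all values are
#'   counts; dimension or key mismatches versus the bin map are errors.
#' @export
read_matrix <- function(path, binmap) {
  assert_that(file.exists(path), paste("no such file:", path))
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  assert_that(names(df)[1] == "bin", "first column must be named 'bin'")
  assert_that(nrow(df) == nrow(binmap),
              "matrix rows do not match the bin map")
  assert_that(all(df$bin == bin_keys(binmap)),
              "bin keys do not match the bin map")
  m <- as.matrix(df[, -1, drop = FALSE])
  assert_that(ncol(m) >= 1, "matrix contains no cell columns")
  read_count_matrix(binmap, m)
}

#' @param x a [read_count_matrix()], [cell_population()] or plain matrix.
#' @rdname read_matrix
#' @export
write_matrix <- function(x, path, binmap = NULL) {
  if (inherits(x, "read_counts")) { binmap <- x$binmap; m <- x$counts }
  else if (inherits(x, "cell_population")) { binmap <- x$binmap; m <- x$profiles }
  else { assert_that(!is.null(binmap), "binmap required for a plain matrix"); m <- x }
  vals <- if (all(m == round(m))) {
    apply(m, 2, function(col) format(as.integer(col), scientific = FALSE))
  } else {
    apply(m, 2, function(col) format(col, digits = 15, scientific = FALSE))
  }
  df <- data.frame(bin = bin_keys(binmap), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("bin", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write spectral-count tables as CSV
#'
#' Columns: protein, condition, replicate, spec_count.
#'
#' @param path CSV path.
#' @param anchor anchor protein ID (default "H4").
#' @return A [spectral_count_table()].
#' @export
read_spectral_counts <- function(path, anchor = "H4") {
  assert_that(file.exists(path), paste("no such file:", path))
  spectral_count_table(read.csv(path, stringsAsFactors = FALSE),
                       anchor = anchor)
}

#' @param table a [spectral_count_table()].
#' @rdname read_spectral_counts
#' @export
write_spectral_counts <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CNA-burden table as TSV
#'
#' Auto-detects the per-chromosome layout (tumor, subtype, chromosome,
#' count) and the pre-summed layout (tumor, subtype, total).
#'
#' @param path TSV path.
#' @return Data.frame in the detected layout (see [sum_autosomal_burden()]).
#' @export
read_burden_table <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  ok <- all(c("tumor", "subtype", "total") %in% names(df)) ||
    all(c("tumor", "subtype", "chromosome", "count") %in% names(df))
  assert_that(ok, "unrecognized burden table layout")
  df
}

#' Export a copy-number profile as BED segments
#'
#' Merges runs of equal copy number on each chromosome into segments and
#' writes chrom, start, end, copy.
#'
#' @param profile integer copy vector over `binmap`.
#' @param binmap a [bin_map()].
#' @param path output path.
#' @export
write_profile_bed <- function(profile, binmap, path) {
  assert_that(length(profile) == nrow(binmap), "profile must cover the bin map")
  key <- paste(binmap$chrom, profile)
  run <- rle(key)
  ends <- cumsum(run$lengths)
  starts <- c(1, head(ends, -1) + 1)
  df <- data.frame(binmap$chrom[starts], as.integer(binmap$start[starts]),
                   as.integer(binmap$end[ends]), profile[starts])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# JSON sidecar embedding the parameters that produced an artifact
write_sidecar <- function(path, params) {
  jsonlite::write_json(
    c(list(package = "CINspect",
           version = as.character(utils::packageVersion("CINspect"))),
      params),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
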