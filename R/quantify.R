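# Count container, RPKM-style normalization, and TSV I/O.

#' Time-course count container
#'
#' Holds raw read hit counts for one embryonic time course: four time bins
#' (0-2, 2-4, 4-8 and 8-12 hr post-oviposition), one library per bin, no
#' replicates. Library sizes default to the column sums but can be supplied
#' explicitly so that a subset matrix (e.g. a few thousand of the annotated
#' transcripts) still carries the true per-sample totals.
#'
#' @param transcript_ids Character vector of unique transcript identifiers.
#' @param lengths_bp Positive integer transcript lengths (bp).
#' @param counts Non-negative integer matrix, transcripts x 4 bins, bin order
#'   0-2, 2-4, 4-8, 8-12 hr.
#' @param library_sizes Four positive totals of mapped hits per bin; defaults
#'   to `colSums(counts)`.
#' @return An object of class `tc_counts`.
#' @export
tc_counts <- function(transcript_ids, lengths_bp, counts,
                      library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  assert_that(ncol(counts) == 4L, "counts must have exactly four time-bin columns")
  assert_that(length(transcript_ids) == nrow(counts),
              "transcript_ids length must match nrow(counts)")
  assert_that(!anyDuplicated(transcript_ids), "duplicate transcript ids")
  assert_that(length(lengths_bp) == nrow(counts),
              "lengths_bp length must match nrow(counts)")
  assert_that(all(is.finite(lengths_bp)) && all(lengths_bp > 0),
              "transcript lengths must be positive")
  assert_that(all(is.finite(counts)) && all(counts >= 0) && all(counts == trunc(counts)),
              "counts must be non-negative integers")
  assert_that(length(library_sizes) == 4L && all(is.finite(library_sizes)) &&
                all(library_sizes > 0),
              "library_sizes must be four positive totals")
  dimnames(counts) <- list(as.character(transcript_ids), BIN_NAMES)
  structure(
    list(transcript_ids = as.character(transcript_ids),
         lengths_bp = as.integer(round(lengths_bp)),
         counts = counts,
         library_sizes = stats::setNames(as.numeric(library_sizes), BIN_NAMES)),
    class = "tc_counts"
  )
}

#' @export
print.tc_counts <- function(x, ...) {
  cat("Time-course counts:", nrow(x$counts), "transcripts x 4 bins",
      paste0("(", paste(BIN_LABELS, collapse = ", "), " hr)\n"))
  cat("Library sizes:", paste(format(x$library_sizes, big.mark = ","),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.tc_counts <- function(x) dim(x$counts)

#' Normalize counts to reads per kilobase per million mapped hits
#'
#' Computes `K / ((length_bp/1000) * (N/1e6))` for raw count `K`, transcript
#' length in bp, and per-sample total hit count `N`. A value is zero exactly
#' when the raw count is zero.
#'
#' @param x A [tc_counts] object.
#' @return Numeric matrix, same shape as `x$counts`, in units of reads per
#'   kilobase per million mappable reads.
#' @examples
#' x <- tc_counts("t1", 1000, matrix(c(10, 0, 5, 2), 1), rep(1e6, 4))
#' normalize_counts(x)[1, 1] # 10
#' @export
normalize_counts <- function(x) {
  assert_that(inherits(x, "tc_counts"), "x must be a tc_counts object")
  kb <- x$lengths_bp / 1000
  per_million <- x$library_sizes / 1e6
  sweep(x$counts / kb, 2L, per_million, "/")
}

#' Read / write time-course counts as TSV
#'
#' The count TSV has columns `transcript_id`, `len_bp`, `h0_2`, `h2_4`,
#' `h4_8`, `h8_12`. Library sizes travel in a two-column companion TSV
#' (`bin`, `library_size`); without it they default to column sums.
#'
#' @param path Path to the counts TSV.
#' @param library_sizes Either `NULL` (use column sums), a numeric vector of
#'   4 totals, or a path to a library-size TSV.
#' @return For `read_counts`, a [tc_counts]; `write_counts` returns `path`
#'   invisibly.
#' @export
read_counts <- function(path, library_sizes = NULL) {
  assert_that(file.exists(path), "counts file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("transcript_id", "len_bp", BIN_NAMES)
  missing <- setdiff(needed, names(df))
  assert_that(length(missing) == 0L,
              "counts TSV is missing column(s): ", paste(missing, collapse = ", "))
  dup <- df$transcript_id[duplicated(df$transcript_id)]
  assert_that(length(dup) == 0L,
              "duplicate transcript id(s) in counts TSV: ",
              paste(utils::head(unique(dup), 5L), collapse = ", "))
  cm <- as.matrix(df[BIN_NAMES])
  bad <- which(!is.finite(cm) | cm < 0 | cm != trunc(cm), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    abort("non-integer or negative count at row ", bad[1L, 1L],
          " (transcript ", df$transcript_id[bad[1L, 1L]], ")",
          class = "ezgkit_validation_error")
  if (is.character(library_sizes)) {
    ls_df <- utils::read.delim(library_sizes, stringsAsFactors = FALSE)
    assert_that(all(c("bin", "library_size") %in% names(ls_df)),
                "library-size TSV needs columns bin, library_size")
    library_sizes <- ls_df$library_size[match(BIN_NAMES, ls_df$bin)]
  }
  tc_counts(df$transcript_id, df$len_bp, cm,
            library_sizes = library_sizes %||% colSums(cm))
}

#' @param x A [tc_counts] object.
#' @param library_size_path Optional path for the companion library-size TSV.
#' @rdname read_counts
#' @export
write_counts <- function(x, path, library_size_path = NULL) {
  assert_that(inherits(x, "tc_counts"), "x must be a tc_counts object")
  df <- data.frame(transcript_id = x$transcript_ids, len_bp = x$lengths_bp,
                   x$counts, check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(library_size_path)) {
    utils::write.table(
      data.frame(bin = BIN_NAMES, library_size = unname(x$library_sizes)),
      library_size_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
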