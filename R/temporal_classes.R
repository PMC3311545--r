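# Presence/absence temporal classification and early-zygotic calling.
#
# A transcript is "present" in a bin when it has at least one read hit.
# Maternal transcripts are present at 0-2 hr; early zygotic candidates are
# absent at 0-2 hr and present at 2-4 hr; later first-presence groups follow
# the same pattern shifted right.

TEMPORAL_LEVELS <- c("maternal", "candidate_2_4", "first_4_8", "first_8_12", "absent")

#' Classify one transcript's four-bin presence pattern
#'
#' @param counts_row Four non-negative counts, bin order 0-2, 2-4, 4-8,
#'   8-12 hr.
#' @return One of `"maternal"`, `"candidate_2_4"`, `"first_4_8"`,
#'   `"first_8_12"`, `"absent"`.
#' @examples
#' classify_transcript(c(0, 1, 5, 10)) # candidate_2_4
#' @export
classify_transcript <- function(counts_row) {
  assert_that(length(counts_row) == 4L, "expected exactly four bin counts")
  assert_that(all(is.finite(counts_row)) && all(counts_row >= 0),
              "counts must be non-negative")
  if (counts_row[1L] >= 1) "maternal"
  else if (counts_row[2L] >= 1) "candidate_2_4"
  else if (counts_row[3L] >= 1) "first_4_8"
  else if (counts_row[4L] >= 1) "first_8_12"
  else "absent"
}

#' Classify every transcript in a count matrix
#'
#' @param x A [tc_counts] object.
#' @return Named factor over the five temporal classes, one per transcript.
#' @export
classify_transcripts <- function(x) {
  assert_that(inherits(x, "tc_counts"), "x must be a tc_counts object")
  present <- x$counts >= 1
  lab <- rep("absent", nrow(present))
  lab[present[, 4L]] <- "first_8_12"
  lab[present[, 3L]] <- "first_4_8"
  lab[present[, 2L]] <- "candidate_2_4"
  lab[present[, 1L]] <- "maternal"
  factor(stats::setNames(lab, x$transcript_ids), levels = TEMPORAL_LEVELS)
}

#' Call early zygotic genes: presence filter intersected with MARS
#'
#' Candidates are transcripts absent at 0-2 hr and present (>= 1 hit) at
#' 2-4 hr. The significant set at threshold `alpha` is the subset with MARS
#' `p_value < alpha` and `m_shift > 0` (expression above its conditional
#' null expectation at the later bin, i.e. a genuine increase -- a two-sided
#' p-value alone does not encode direction).
#'
#' @param x A [tc_counts] object.
#' @param mars_results A [mars_table] computed on the (0-2, 2-4) bin pair.
#' @param thresholds Ascending raw p-value thresholds; defaults
#'   `c(0.001, 0.05)`. Significant sets are nested across thresholds.
#' @return List with `candidates` (character vector of transcript ids) and
#'   `significant` (named list, one id vector per threshold).
#' @export
call_ezgs <- function(x, mars_results, thresholds = c(0.001, 0.05)) {
  assert_that(inherits(x, "tc_counts"), "x must be a tc_counts object")
  assert_that(is.data.frame(mars_results) &&
                all(c("transcript_id", "p_value", "m_shift") %in% names(mars_results)),
              "mars_results must come from mars_table()")
  bp <- attr(mars_results, "bin_pair")
  if (!is.null(bp))
    assert_that(identical(unname(bp), c("h0_2", "h2_4")),
                "mars_results must be computed on the (0-2, 2-4) bin pair")
  assert_that(setequal(mars_results$transcript_id, x$transcript_ids),
              "mars_results and counts cover different transcript sets")
  assert_that(!is.unsorted(thresholds), "thresholds must be ascending")

  cls <- classify_transcripts(x)
  candidates <- names(cls)[cls == "candidate_2_4"]
  idx <- match(mars_results$transcript_id, x$transcript_ids)
  up <- mars_results$m_shift > 0
  significant <- lapply(thresholds, function(alpha) {
    hit <- mars_results$transcript_id[mars_results$p_value < alpha & up]
    intersect(candidates, hit)
  })
  names(significant) <- as.character(thresholds)
  list(candidates = candidates, significant = significant)
}

#' Group transcripts by first presence, gated by MARS significance
#'
#' Mirrors the definition of the 2-4, 4-8 and 8-12 hr first-presence groups:
#' a transcript joins the group of the bin where it first shows >= 1 hit
#' (with no hits in any earlier bin) provided its increase over the
#' preceding bin is MARS-significant at `threshold`. The baseline bin for
#' each comparison is the adjacent preceding bin by default.
#'
#' @param x A [tc_counts] object.
#' @param threshold Raw p-value threshold (default 0.001).
#' @param pseudocount Passed to [mars_table].
#' @param baseline `"preceding"` (default) compares each first-presence bin
#'   against the bin before it; `"h0_2"` always uses the 0-2 hr bin.
#' @return Named list of disjoint transcript-id vectors:
#'   `h2_4`, `h4_8`, `h8_12`.
#' @export
group_by_first_presence <- function(x, threshold = 0.001, pseudocount = 1,
                                    baseline = c("preceding", "h0_2")) {
  assert_that(inherits(x, "tc_counts"), "x must be a tc_counts object")
  baseline <- match.arg(baseline)
  cls <- classify_transcripts(x)
  first_bin <- c(candidate_2_4 = 2L, first_4_8 = 3L, first_8_12 = 4L)
  out <- lapply(names(first_bin), function(lab) {
    j <- first_bin[[lab]]
    base_bin <- if (baseline == "preceding") BIN_NAMES[j - 1L] else "h0_2"
    mt <- mars_table(x, bin_pair = c(base_bin, BIN_NAMES[j]),
                     pseudocount = pseudocount)
    ok <- mt$transcript_id[mt$p_value < threshold & mt$m_shift > 0]
    intersect(names(cls)[cls == lab], ok)
  })
  names(out) <- BIN_NAMES[first_bin]
  out
}

#' Collapse a transcript set to distinct genes
#'
#' Several transcripts can share a gene (alternative isoforms); headline
#' gene counts use distinct gene ids with the first-listed transcript as the
#' representative.
#'
#' @param transcript_ids Character vector of transcript ids.
#' @param annotations Annotation data frame with `transcript_id`, `gene_id`.
#' @return Data frame with one row per distinct gene: `gene_id`,
#'   `representative_transcript`, `n_transcripts`.
#' @export
collapse_to_genes <- function(transcript_ids, annotations) {
  assert_that(all(c("transcript_id", "gene_id") %in% names(annotations)),
              "annotations need transcript_id and gene_id columns")
  idx <- match(transcript_ids, annotations$transcript_id)
  missing <- transcript_ids[is.na(idx)]
  assert_that(length(missing) == 0L, "unannotated transcript(s): ",
              paste(utils::head(missing, 5L), collapse = ", "))
  genes <- annotations$gene_id[idx]
  first <- !duplicated(genes)
  data.frame(gene_id = genes[first],
             representative_transcript = transcript_ids[first],
             n_transcripts = as.vector(table(genes)[genes[first]]),
             row.names = NULL)
}

#' Write the temporal classification table as TSV
#'
#' @param x A [tc_counts] object.
#' @param mars_results A [mars_table] on the (0-2, 2-4) pair.
#' @param path Output path.
#' @param thresholds Thresholds for the membership indicator columns.
#' @export
write_classification <- function(x, mars_results, path,
                                 thresholds = c(0.001, 0.05)) {
  cls <- classify_transcripts(x)
  calls <- call_ezgs(x, mars_results, thresholds)
  idx <- match(x$transcript_ids, mars_results$transcript_id)
  out <- data.frame(transcript_id = x$transcript_ids,
                    class = as.character(cls),
                    p_value = mars_results$p_value[idx])
  for (th in as.character(thresholds))
    out[[paste0("ezg_p", th)]] <- out$transcript_id %in% calls$significant[[th]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
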