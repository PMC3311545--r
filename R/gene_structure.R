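# Gene structure: intronless scoring per gene and enrichment tests.
#
# Early zygotic gene sets are enriched for intronless genes, consistent
# with selection for rapid transcription during fast early nuclear cycles.

#' Read a transcript annotation table
#'
#' Accepts either a TSV with columns `transcript_id`, `gene_id`,
#' `n_introns`, `length_bp`, or a GFF3 file in which case introns are
#' inferred per transcript as (exon count - 1) and length as the summed
#' exon width (requires the rtracklayer package).
#'
#' @param path Path to a TSV or GFF3 file.
#' @return Data frame with the four annotation columns.
#' @export
read_annotations <- function(path) {
  assert_that(file.exists(path), "annotation file not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      abort("reading GFF3 annotations requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    ex <- gr[gr$type == "exon"]
    parent <- vapply(ex$Parent, function(p) p[1L], "")
    exon_n <- table(parent)
    exon_len <- tapply(BiocGenerics::width(ex), parent, sum)
    tx <- gr[gr$type %in% c("mRNA", "transcript")]
    tx_id <- tx$ID
    gene_id <- vapply(tx$Parent, function(p) if (length(p)) p[1L] else NA_character_, "")
    df <- data.frame(
      transcript_id = tx_id,
      gene_id = gene_id,
      n_introns = as.integer(exon_n[tx_id]) - 1L,
      length_bp = as.integer(exon_len[tx_id]),
      row.names = NULL)
    assert_that(!anyNA(df$n_introns), "GFF3 transcript(s) with no exon records")
    return(df)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("transcript_id", "gene_id", "n_introns", "length_bp")
  missing <- setdiff(needed, names(df))
  assert_that(length(missing) == 0L,
              "annotation TSV is missing column(s): ", paste(missing, collapse = ", "))
  df[needed]
}

#' Score genes as intronless from their transcripts
#'
#' A transcript either has at least one intron or none. Under the default
#' `"all"` rule a gene is intronless only if every cognate transcript is
#' intronless (the conservative reading); `"any"` calls a gene intronless
#' if any transcript is.
#'
#' @param annotations Data frame with `transcript_id`, `gene_id`,
#'   `n_introns`.
#' @param rule `"all"` (default) or `"any"`.
#' @return Named logical vector, one entry per gene.
#' @export
gene_intron_status <- function(annotations, rule = c("all", "any")) {
  rule <- match.arg(rule)
  assert_that(all(c("transcript_id", "gene_id", "n_introns") %in% names(annotations)),
              "annotations need transcript_id, gene_id, n_introns columns")
  bad <- annotations$transcript_id[is.na(annotations$gene_id) | annotations$gene_id == ""]
  assert_that(length(bad) == 0L, "transcript(s) with unknown gene: ",
              paste(utils::head(bad, 5L), collapse = ", "))
  assert_that(all(is.finite(annotations$n_introns)) && all(annotations$n_introns >= 0),
              "n_introns must be non-negative")
  intronless_tx <- annotations$n_introns == 0L
  agg <- if (rule == "all") tapply(intronless_tx, annotations$gene_id, all)
         else tapply(intronless_tx, annotations$gene_id, any)
  res <- as.logical(agg)
  names(res) <- names(agg)
  res
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param a,b,c,d Cell counts, row-wise: `(a, b)` is the first row (e.g.
#'   intronless / with-introns in the focal group), `(c, d)` the second
#'   (same split in the comparison group).
#' @param yates Apply Yates continuity correction (off by default; the
#'   in-scope comparisons have large counts).
#' @return List with `statistic` (1-df chi-squared) and `p_value`
#'   (upper-tail).
#' @export
chi2_2x2 <- function(a, b, c, d, yates = FALSE) {
  cells <- as.numeric(c(a, b, c, d))  # doubles: margin products overflow int
  a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
  assert_that(all(is.finite(cells)) && all(cells >= 0), "counts must be non-negative")
  n <- sum(cells)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  assert_that(all(c(r1, r2, c1, c2) > 0), "all margins of the 2x2 table must be > 0")
  delta <- abs(a * d - b * c)
  if (yates) delta <- max(0, delta - n / 2)
  stat <- n * delta^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Summarize intron content per group and test enrichment
#'
#' Produces one summary row per group (plus `"all"`) and a chi-squared test
#' of each group's intronless fraction against the remaining genes. The
#' per-gene intron count for the mean uses the maximum across a gene's
#' transcripts by default (a gene "has" an intron if any transcript does).
#'
#' @param annotations Annotation data frame (see [gene_intron_status]).
#' @param groups Named list of gene-id vectors, e.g. the EZG / 4-8 hr /
#'   8-12 hr first-presence sets collapsed to genes.
#' @param rule Intronless rule passed to [gene_intron_status].
#' @param intron_summary `"max"` (default) or `"mean"`: how a multi-
#'   transcript gene's intron count is summarized before averaging.
#' @param yates Passed to [chi2_2x2].
#' @return List with `summary` (data frame: group, n_genes, n_intronless,
#'   fraction_intronless, mean_introns_per_gene) and `tests` (data frame:
#'   group, chi2, p_value vs the rest).
#' @export
compare_groups <- function(annotations, groups, rule = "all",
                           intron_summary = c("max", "mean"), yates = FALSE) {
  intron_summary <- match.arg(intron_summary)
  status <- gene_intron_status(annotations, rule)
  fun <- if (intron_summary == "max") max else mean
  introns_per_gene <- tapply(annotations$n_introns, annotations$gene_id, fun)
  all_genes <- names(status)

  unknown <- setdiff(unlist(groups, use.names = FALSE), all_genes)
  assert_that(length(unknown) == 0L, "group gene(s) not in annotations: ",
              paste(utils::head(unknown, 5L), collapse = ", "))

  summarize <- function(ids) {
    n <- length(ids)
    ni <- sum(status[ids])
    data.frame(n_genes = n, n_intronless = ni,
               fraction_intronless = if (n > 0) ni / n else NA_real_,
               mean_introns_per_gene = if (n > 0) mean(introns_per_gene[ids]) else NA_real_)
  }
  summary <- do.call(rbind, c(
    list(cbind(data.frame(group = "all"), summarize(all_genes))),
    lapply(names(groups), function(g)
      cbind(data.frame(group = g), summarize(groups[[g]])))
  ))
  tests <- do.call(rbind, lapply(names(groups), function(g) {
    ids <- groups[[g]]
    rest <- setdiff(all_genes, ids)
    if (length(ids) == 0L || length(rest) == 0L)
      return(data.frame(group = g, chi2 = NA_real_, p_value = NA_real_))
    ct <- chi2_2x2(sum(status[ids]), sum(!status[ids]),
                   sum(status[rest]), sum(!status[rest]), yates = yates)
    data.frame(group = g, chi2 = ct$statistic, p_value = ct$p_value)
  }))
  list(summary = summary, tests = tests)
}
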