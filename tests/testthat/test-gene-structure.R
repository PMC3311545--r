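test_that("gene intronless status follows the transcript rule", {
  ann <- data.frame(transcript_id = c("t1", "t2", "t3", "t4", "t5"),
                    gene_id = c("g1", "g1", "g2", "g2", "g3"),
                    n_introns = c(0L, 0L, 0L, 2L, 3L))
  all_rule <- gene_intron_status(ann)
  expect_identical(all_rule, c(g1 = TRUE, g2 = FALSE, g3 = FALSE))
  any_rule <- gene_intron_status(ann, rule = "any")
  expect_identical(any_rule, c(g1 = TRUE, g2 = TRUE, g3 = FALSE))

  ann$gene_id[2] <- NA
  expect_error(gene_intron_status(ann), "unknown gene.*t2")
})

test_that("chi-squared matches the closed form and the stats oracle", {
  r <- chi2_2x2(10, 10, 10, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # direct evaluation of sum((O-E)^2/E) as an independent oracle
  direct <- function(a, b, c, d) {
    O <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    sum((O - E)^2 / E)
  }
  got <- chi2_2x2(20, 41, 1679, 15110)
  expect_equal(got$statistic, direct(20, 41, 1679, 15110), tolerance = 1e-12)
  expect_lt(got$p_value, 1e-4)

  # transposition invariance
  tr <- chi2_2x2(20, 1679, 41, 15110)
  expect_equal(tr$statistic, got$statistic)

  # random tables vs stats::chisq.test, with and without Yates
  withr::with_seed(TEST_SEED, {
    for (i in 1:100) {
      cell <- rpois(4, 30) + 1
      mine <- chi2_2x2(cell[1], cell[2], cell[3], cell[4])
      ref <- suppressWarnings(
        stats::chisq.test(matrix(cell, 2, byrow = TRUE), correct = FALSE))
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
      yates <- chi2_2x2(cell[1], cell[2], cell[3], cell[4], yates = TRUE)
      refy <- suppressWarnings(
        stats::chisq.test(matrix(cell, 2, byrow = TRUE), correct = TRUE))
      expect_equal(yates$statistic, unname(refy$statistic), tolerance = 1e-9)
    }
  })
  expect_error(chi2_2x2(0, 0, 5, 5), "margins")
})

test_that("group comparison summarizes and tests against the rest", {
  ann <- data.frame(transcript_id = sprintf("t%d", 1:6),
                    gene_id = sprintf("g%d", c(1, 1, 2, 3, 4, 5)),
                    n_introns = c(0L, 2L, 0L, 0L, 1L, 4L))
  res <- compare_groups(ann, list(focal = c("g2", "g3")))
  s <- res$summary
  expect_identical(s$group, c("all", "focal"))
  expect_equal(s$n_genes, c(5L, 2L))
  expect_equal(s$n_intronless, c(2L, 2L))   # g2, g3 intronless; g1 mixed
  expect_equal(s$fraction_intronless, c(2 / 5, 1))
  # mean introns per gene with the max-over-transcripts rule:
  # g1 -> 2, g2 -> 0, g3 -> 0, g4 -> 1, g5 -> 4
  expect_equal(s$mean_introns_per_gene, c(mean(c(2, 0, 0, 1, 4)), 0))

  # invariance to transcript ordering
  res2 <- compare_groups(ann[sample(6), ], list(focal = c("g2", "g3")))
  expect_equal(res2$summary, s)

  # empty group yields an NA test
  e <- compare_groups(ann, list(none = character(0)))
  expect_equal(e$summary$n_genes[2], 0L)
  expect_true(is.na(e$tests$p_value))
  expect_error(compare_groups(ann, list(bad = "gX")), "not in annotations")
})

test_that("annotation reading supports TSV and GFF3", {
  ann <- data.frame(transcript_id = c("tA", "tB"), gene_id = c("gA", "gB"),
                    n_introns = c(0L, 2L), length_bp = c(900L, 1500L))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ann, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_annotations(tsv), ann)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t5000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1\t5000\t.\t+\t.\tID=tA;Parent=gA",
    "chr1\tsrc\texon\t1\t900\t.\t+\t.\tParent=tA",
    "chr1\tsrc\tgene\t6000\t9000\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t6000\t9000\t.\t-\t.\tID=tB;Parent=gB",
    "chr1\tsrc\texon\t6000\t6499\t.\t-\t.\tParent=tB",
    "chr1\tsrc\texon\t7000\t7499\t.\t-\t.\tParent=tB",
    "chr1\tsrc\texon\t8000\t8499\t.\t-\t.\tParent=tB"), gff)
  g <- read_annotations(gff)
  g <- g[order(g$transcript_id), ]
  expect_identical(g$transcript_id, c("tA", "tB"))
  expect_identical(g$n_introns, c(0L, 2L))   # exon count - 1
  expect_identical(g$length_bp, c(900L, 1500L))
})
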