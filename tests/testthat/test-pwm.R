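test_that("consensus-derived PWMs are uniform over allowed bases", {
  p <- pwm_from_iupac("V")
  expect_equal(unname(p$matrix[, 1]), c(1/3, 1/3, 1/3, 0))
  g <- pwm_from_iupac("G")
  expect_equal(unname(g$matrix[, 1]), c(0, 0, 1, 0))
  v <- pwm_from_iupac("VBRGGTA")
  expect_equal(ncol(v$matrix), 7L)
  expect_equal(colSums(v$matrix), rep(1, 7), ignore_attr = TRUE)
  expect_equal(unname(v$matrix[, 2]), c(0, 1/3, 1/3, 1/3))  # B
  expect_equal(unname(v$matrix[, 3]), c(1/2, 0, 1/2, 0))    # R
})

test_that("PWMs from hits reproduce a hand-counted stack", {
  seqs <- c(s1 = "GGTAAAAA", s2 = "AGGTATTT", s3 = "TTTTACCT")
  hits <- data.frame(seq_id = c("s1", "s2", "s3"),
                     start = c(0L, 1L, 3L),
                     strand = c("+", "+", "-"))
  # stacked sites: GGTA, GGTA, revcomp(TACC) = GGTA -> columns one-hot
  p <- pwm_from_hits(hits, seqs, motif_length = 4)
  expect_equal(p$n_sites, 3L)
  # counting oracle with pseudocount 0.25: (3 + .25)/(3 + 1) and .25/4
  expect_equal(unname(p$matrix["G", 1]), 3.25 / 4)
  expect_equal(unname(p$matrix["A", 1]), 0.25 / 4)
  expect_equal(unname(p$matrix["A", 4]), 3.25 / 4)
  expect_equal(colSums(p$matrix), rep(1, 4), ignore_attr = TRUE)

  # columns renormalize for any pseudocount
  for (pc in c(0, 0.5, 2)) {
    q <- pwm_from_hits(hits, seqs, motif_length = 4, pseudocount = pc)
    expect_equal(colSums(q$matrix), rep(1, 4), ignore_attr = TRUE)
  }
  expect_error(pwm_from_hits(hits[0, ], seqs, 4), "at least one")
})

test_that("alignment basics: self-alignment, symmetry, revcomp invariance", {
  one_hot <- pwm_from_iupac("GGTACG")
  self <- align_pwms(one_hot, one_hot)
  expect_equal(self$score, 1)
  expect_equal(self$offset, 0L)
  expect_identical(self$orientation, "forward")
  expect_equal(self$n_overlap, 6L)

  q <- pwm_from_iupac("VBRGGTA")
  t <- pwm_from_iupac("YAGGTAG")
  expect_equal(align_pwms(q, t)$score, align_pwms(t, q)$score)
  expect_equal(align_pwms(pwm_revcomp(q), pwm_revcomp(t))$score,
               align_pwms(q, t)$score)
  expect_error(align_pwms(pwm_from_iupac("ACG"), t), "min_overlap")
})

test_that("TAGteam comparison reproduces the derived column-correlation oracle", {
  q <- pwm_from_iupac("VBRGGTA")
  # independent oracle: mean stats::cor over the aligned column pairs
  # B-R-G-G-T-A (query cols 2:7) against the six target columns
  oracle <- function(target) {
    tm <- pwm_from_iupac(target)$matrix
    mean(vapply(1:6, function(j) stats::cor(q$matrix[, j + 1], tm[, j]), 0))
  }
  a_tag <- align_pwms(q, pwm_from_iupac("TAGGTAG"))
  expect_equal(a_tag$score, oracle("TAGGTAG"), tolerance = 1e-12)
  expect_equal(a_tag$score, 0.818, tolerance = 1e-3)
  expect_equal(a_tag$offset, 1L)

  a_cag <- align_pwms(q, pwm_from_iupac("CAGGCAG"))
  expect_equal(a_cag$score, oracle("CAGGCAG"), tolerance = 1e-12)
  expect_equal(a_cag$score, 0.596, tolerance = 1e-3)

  # ordering mirrors the reported E-value ordering: TAGGTAG best, CAGGCAG worst
  expect_gt(a_tag$score, a_cag$score)
})

test_that("empirical E-values are seeded, bounded and score-monotone", {
  q <- pwm_from_iupac("VBRGGTA")
  self <- pwm_alignment_evalue(q, q, n_null = 200, seed = TEST_SEED)
  expect_equal(self$score, 1)
  # self-alignment should beat essentially every permuted null
  expect_lte(self$p_empirical, 5 / 200)

  rnd <- withr::with_seed(TEST_SEED, {
    m <- matrix(rgamma(28, 1), 4, 7)
    pwm(sweep(m, 2, colSums(m), "/"), name = "rand")
  })
  far <- pwm_alignment_evalue(q, rnd, n_null = 200, seed = TEST_SEED)
  expect_gt(far$p_empirical, self$p_empirical)
  expect_equal(far$e_value, 200 * far$p_empirical)

  again <- pwm_alignment_evalue(q, rnd, n_null = 200, seed = TEST_SEED)
  expect_identical(far$e_value, again$e_value)
})

test_that("MEME round-trip preserves matrices and site counts", {
  p1 <- pwm_from_iupac("VBRGGTA")
  seqs <- c(s1 = "GGTAAAAA", s2 = "AGGTATTT")
  p2 <- pwm_from_hits(data.frame(seq_id = c("s1", "s2"), start = c(0L, 1L),
                                 strand = c("+", "+")),
                      seqs, motif_length = 4, name = "hits4")
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(p1, p2), path)
  back <- read_meme(path)
  expect_named(back, c("VBRGGTA", "hits4"))
  expect_equal(back$VBRGGTA$matrix, p1$matrix, tolerance = 1e-5)
  expect_equal(back$hits4$matrix, p2$matrix, tolerance = 1e-5)
  expect_equal(back$hits4$n_sites, 2L)
})
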