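test_that("IUPAC expansion and reverse complement behave", {
  expect_length(iupac_expand("VBRGGTA"), 18L)   # 3 * 3 * 2
  expect_identical(iupac_expand("ACGT"), "ACGT")
  expect_setequal(iupac_expand("N"), c("A", "C", "G", "T"))
  expect_identical(iupac_revcomp("VBRGGTA"), "TACCYVB")
  expect_identical(iupac_revcomp("ACGT"), "ACGT")  # palindrome
  expect_error(iupac_motif("VBXGGTA"), "invalid IUPAC")
  expect_error(iupac_motif(""), "non-empty")

  # involution and expansion-set consistency on random patterns
  withr::with_seed(TEST_SEED, {
    codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
    for (i in 1:25) {
      pat <- paste(sample(codes, sample(4:8, 1), replace = TRUE), collapse = "")
      expect_identical(iupac_revcomp(iupac_revcomp(pat)), pat)
      rc_words <- sort(as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(iupac_expand(pat)))))
      expect_identical(sort(iupac_expand(iupac_revcomp(pat))), rc_words)
    }
  })
})

test_that("scanner matches definition cases and a regex oracle", {
  # C in V, T in B, A in R, then literal GGTA
  hit <- scan_motif("VBRGGTA", c(s1 = "CTAGGTA"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 0L)
  expect_equal(hit$strand, "+")
  # position 2 A is not in B = C/G/T
  expect_equal(nrow(scan_motif("VBRGGTA", c(s1 = "CAGGTAG"))), 0L)
  # motif longer than the sequence: no hits, not an error
  expect_equal(nrow(scan_motif("VBRGGTA", c(s1 = "ACG"))), 0L)

  seqs <- random_seqs(30, 300)
  got <- scan_motif("VBRGGTA", seqs)
  want <- regex_scan("VBRGGTA", as.list(seqs))
  expect_equal(got$start, want$start)
  expect_equal(got$seq_id, want$seq_id)
  expect_equal(got$strand, want$strand)

  # strand-flip property: scanning the revcomp flips strands only
  flip <- scan_motif(iupac_revcomp("VBRGGTA"), seqs)
  expect_equal(flip$start, got$start)
  expect_equal(flip$strand, chartr("+-", "-+", got$strand))
})

test_that("window probability equals the expansion-set enumeration", {
  bg <- c(A = 0.31, C = 0.19, G = 0.19, T = 0.31)
  for (pat in c("VBRGGTA", "RYSWKM", "ACGT", "NNN", "GGWCC")) {
    enum <- sum(vapply(iupac_expand(pat), function(w)
      prod(bg[strsplit(w, "")[[1]]]), 0))
    expect_equal(ezgkit:::motif_prob(pat, bg), enum, tolerance = 1e-12)
  }
  # either-orientation probability with inclusion-exclusion, by enumeration
  for (pat in c("GGWCC", "ACGT", "VBRGGTA")) {
    fwd <- iupac_expand(pat)
    rev <- iupac_expand(iupac_revcomp(pat))
    enum <- sum(vapply(union(fwd, rev), function(w)
      prod(bg[strsplit(w, "")[[1]]]), 0))
    expect_equal(ezgkit:::window_prob(pat, bg), enum, tolerance = 1e-12)
  }
})

test_that("motif statistics: counts, coverage, sign conventions", {
  seqs <- c(a = "AAGGTACCTT", b = "TTTTTTTTTT", c = "AAGGTAAAAA", d = "CCCCCCCCCC")
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  st <- motif_stats("GGTA", seqs, background = bg, n_candidates_tested = 100)
  # a: GGTA at 2(+) and its revcomp TACC at 5 (-); c: one at 2(+)
  expect_equal(st$count, 3L)
  expect_equal(st$coverage, 0.5)
  # absent motif: tail is 1, E = n_candidates, sig negative
  none <- motif_stats("GGATCC", seqs, background = bg, n_candidates_tested = 100)
  expect_equal(none$count, 0L)
  expect_equal(none$e_value, 100)
  expect_equal(none$sig_value, -2)

  # sig_value is monotone increasing in the observed count
  sigs <- vapply(c(5, 10, 20, 40), function(x)
    ezgkit:::motif_sig(x, 1000, 0.01, 50)$sig_value, 0)
  expect_true(all(diff(sigs) > 0))

  # count >= number of covered sequences
  expect_gte(st$count, st$coverage * 4)
})

test_that("word-table counting is identical to full scanning", {
  seqs <- random_seqs(20, 200, seed = TEST_SEED + 1)
  dna <- Biostrings::DNAStringSet(seqs)
  withr::with_seed(TEST_SEED, {
    pats <- c("VBRGGTA", "GGWCC", "RYSWK", "AACGTT", "SWS",
              replicate(10, paste(sample(c("A", "C", "G", "T", "R", "Y", "S",
                                           "W", "B", "V"),
                                         sample(5:8, 1), replace = TRUE),
                                  collapse = "")))
  })
  for (pat in pats) {
    L <- nchar(pat)
    wt <- ezgkit:::word_table(unname(seqs), L)
    lookup <- ezgkit:::word_lookup(wt)
    fast <- ezgkit:::pattern_counts_from_table(pat, lookup)
    slow <- ezgkit:::count_motif(pat, dna)
    expect_identical(fast$count, slow$count)
    expect_identical(fast$n_windows_hit, slow$n_windows_hit)
    expect_equal(slow$count, nrow(scan_motif(pat, dna)))
  }
})

test_that("discovery recovers a strongly planted exact word and is deterministic", {
  # plant a fixed 7-mer in 80% of 40 sequences on mixed strands
  word <- "TAGGTCA"
  seqs <- random_seqs(40, 150, seed = TEST_SEED + 2)
  withr::with_seed(TEST_SEED + 3, {
    for (i in sample(40, 32)) {
      pos <- sample(144, 1)
      ins <- if (runif(1) < 0.5) word else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(word)))
      substr(seqs[i], pos, pos + 6) <- ins
    }
  })
  res <- discover_motifs(seqs, length_range = c(7, 7), beam_width = 20)
  expect_gte(expansion_jaccard(res$motif[1], word), 0.5)
  expect_gte(res$sig_value[1], 2)
  expect_identical(res$algorithm %in% c("beam", "prism"), rep(TRUE, nrow(res)))

  res2 <- discover_motifs(seqs, length_range = c(7, 7), beam_width = 20)
  expect_identical(res, res2)

  expect_error(discover_motifs(seqs["r001"]), "at least two")
})

test_that("query evaluation handles sets and empty input", {
  seqs <- random_seqs(10, 120)
  out <- evaluate_query("VBRGGTA", list(a = seqs, b = seqs))
  expect_equal(out$set, c("a", "b"))
  expect_equal(out$sig_value[1], out$sig_value[2])
  expect_error(evaluate_query("VBRGGTA", list(a = character(0))), "empty")
})

test_that("hits export as BED6", {
  seqs <- c(s1 = "AAGGTACC")
  hits <- scan_motif("GGTA", seqs)
  path <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, "GGTA", path)
  bed <- utils::read.delim(path, header = FALSE)
  expect_equal(ncol(bed), 6L)
  expect_equal(bed$V3 - bed$V2, rep(4L, nrow(bed)))
  expect_true(all(bed$V6 %in% c("+", "-")))
})
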