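# Shared fixtures and independent oracles, built in code at test time.

# Canonical test seed, fixed once for the whole suite.
TEST_SEED <- 1L

# A small, fast simulation scenario preserving the stated class structure.
test_config <- function(seed = TEST_SEED,
                        library_sizes = c(4e5, 4.5e5, 5e5, 4.2e5), ...) {
  sim_config(n_transcripts = 3000, library_sizes = library_sizes,
             seed = seed, ...)
}

# Tiny hand-built count container.
toy_counts <- function() {
  tc_counts(transcript_ids = c("t1", "t2", "t3"),
            lengths_bp = c(1000, 517, 2000),
            counts = rbind(c(10, 0, 5, 2),
                           c(0, 7, 3, 1),
                           c(0, 0, 0, 4)),
            library_sizes = c(1e6, 3.2e6, 2e6, 1.5e6))
}

# Independent regex scanner: all (overlapping) both-strand matches of an
# IUPAC motif, minus-strand hits anchored at their plus-strand start.
regex_scan <- function(pattern, seqs) {
  iupac_regex <- function(p) {
    sets <- list(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
    paste0("(?=", paste0("[", sets[strsplit(p, "")[[1]]], "]", collapse = ""), ")")
  }
  one <- function(p, strand) {
    do.call(rbind, lapply(names(seqs), function(id) {
      m <- gregexpr(iupac_regex(p), seqs[[id]], perl = TRUE)[[1]]
      if (m[1] == -1) return(NULL)
      data.frame(seq_id = id, start = as.integer(m) - 1L, strand = strand)
    }))
  }
  rc <- function(p) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
              N = "N")
    paste(rev(comp[strsplit(p, "")[[1]]]), collapse = "")
  }
  out <- rbind(one(pattern, "+"), one(rc(pattern), "-"))
  if (is.null(out))
    return(data.frame(seq_id = character(0), start = integer(0),
                      strand = character(0)))
  out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
}

# Random i.i.d. DNA as a named character vector.
random_seqs <- function(n, len, gc = 0.4, seed = TEST_SEED) {
  withr::with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    setNames(vapply(seq_len(n), function(i)
      paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""), ""),
      sprintf("r%03d", seq_len(n)))
  })
}

# Expansion-set Jaccard between two motifs, best over the second motif's
# two orientations (both-strand scanning makes them one hypothesis).
expansion_jaccard <- function(a, b) {
  ea <- iupac_expand(a)
  j <- function(bb) {
    eb <- iupac_expand(bb)
    length(intersect(ea, eb)) / length(union(ea, eb))
  }
  max(j(b), j(iupac_revcomp(b)))
}
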