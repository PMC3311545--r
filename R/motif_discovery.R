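# Discovery and evaluation of overrepresented degenerate promoter motifs.
#
# Significance model: each length-L window of the sequence set is one
# Bernoulli trial that succeeds when the window matches the motif in either
# orientation, with success probability p(m) + p(rc m) - p(both) under an
# order-0 background. The observed statistic X is the number of distinct
# matching windows; for a motif whose expansion set is disjoint from its
# reverse complement's (the generic case) X equals the both-strand
# occurrence total. The E-value multiplies the exact binomial upper tail by
# the number of candidate motifs examined (Bonferroni-style) and the
# reported significance is -log10(E): negative whenever the motif is at or
# below background expectation, as observed for query searches on control
# sets. The reported Count remains the total of occurrences on both strands
# (a self-complementary match is listed once per strand).

#' Order-0 background model from a sequence set
#'
#' @param sequences A [Biostrings::DNAStringSet] (or named character vector).
#' @param floor Lower bound applied to each frequency before renormalizing.
#' @return Named numeric vector of A/C/G/T frequencies summing to 1.
#' @export
background_model <- function(sequences, floor = 1e-6) {
  sequences <- as_dna_set(sequences)
  assert_that(length(sequences) > 0L, "empty sequence set")
  freq <- colSums(Biostrings::alphabetFrequency(sequences)[, c("A", "C", "G", "T"),
                                                           drop = FALSE])
  assert_that(sum(freq) > 0, "sequences contain no unambiguous bases")
  p <- pmax(freq / sum(freq), floor)
  p / sum(p)
}

as_dna_set <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) return(sequences)
  Biostrings::DNAStringSet(toupper(sequences))
}

# P(motif matches at one position) under an order-0 background: product over
# positions of the summed frequencies of the allowed bases. Equal to the sum
# of word probabilities over the expansion set.
motif_prob <- function(pattern, background) {
  chars <- strsplit(iupac_motif(pattern), "", fixed = TRUE)[[1L]]
  prod(vapply(IUPAC_SETS[chars], function(s) sum(background[s]), 0))
}

#' Scan a sequence set for a degenerate motif on both strands
#'
#' Reports every (possibly overlapping) match of the motif or its reverse
#' complement. Minus-strand hits are anchored at their plus-strand start;
#' coordinates are 0-based. A self-reverse-complementary motif matching at
#' one position is reported on both strands (it counts twice, consistent
#' with "total occurrences on both strands"). An `N` in a *sequence*
#' matches nothing. Sequences shorter than the motif simply yield no hits.
#'
#' @param pattern IUPAC motif string.
#' @param sequences Named [Biostrings::DNAStringSet] or character vector.
#' @return Data frame of hits: `seq_id`, `start` (0-based), `strand`.
#' @export
scan_motif <- function(pattern, sequences) {
  pattern <- iupac_motif(pattern)
  sequences <- as_dna_set(sequences)
  if (is.null(names(sequences))) names(sequences) <- sprintf("seq%d", seq_along(sequences))
  one_strand <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, sequences, fixed = "subject")
    starts <- lapply(m, Biostrings::start)
    n_per <- lengths(starts)
    data.frame(seq_id = rep(names(sequences), n_per),
               start = unlist(starts, use.names = FALSE) - 1L,
               strand = rep(strand, sum(n_per)))
  }
  plus <- one_strand(pattern, "+")
  minus <- one_strand(iupac_revcomp(pattern), "-")
  out <- rbind(plus, minus)
  out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
}

# Per-position IUPAC code of the intersection of a motif with its reverse
# complement, or NULL if any position's base sets are disjoint (in which
# case no window can match both orientations).
self_overlap_pattern <- function(pattern) {
  a <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  b <- strsplit(iupac_revcomp(pattern), "", fixed = TRUE)[[1L]]
  codes <- character(length(a))
  for (j in seq_along(a)) {
    both <- intersect(IUPAC_SETS[[a[j]]], IUPAC_SETS[[b[j]]])
    if (length(both) == 0L) return(NULL)
    codes[j] <- iupac_code_for(both)
  }
  paste(codes, collapse = "")
}

# Fast both-strand counts, distinct matching windows, and per-sequence
# coverage without materializing hit positions.
count_motif <- function(pattern, sequences) {
  sequences <- as_dna_set(sequences)
  cp <- Biostrings::vcountPattern(pattern, sequences, fixed = "subject")
  cm <- Biostrings::vcountPattern(iupac_revcomp(pattern), sequences, fixed = "subject")
  overlap <- self_overlap_pattern(pattern)
  cb <- if (is.null(overlap)) 0L
        else Biostrings::vcountPattern(overlap, sequences, fixed = "subject")
  list(count = sum(cp) + sum(cm),          # both-strand occurrence total
       n_windows_hit = sum(cp) + sum(cm) - sum(cb), # distinct windows
       covered = sum(cp + cm > 0))
}

# Success probability of one window under the order-0 background: match in
# either orientation.
window_prob <- function(pattern, background) {
  p_fwd <- motif_prob(pattern, background)
  p_rev <- motif_prob(iupac_revcomp(pattern), background)
  overlap <- self_overlap_pattern(pattern)
  p_both <- if (is.null(overlap)) 0 else motif_prob(overlap, background)
  p_fwd + p_rev - p_both
}

#' Write motif hits as BED6
#'
#' @param hits Data frame from [scan_motif].
#' @param pattern Motif pattern (becomes the BED name field).
#' @param path Output path.
#' @export
write_hits_bed <- function(hits, pattern, path) {
  L <- nchar(iupac_motif(pattern))
  bed <- data.frame(chrom = hits$seq_id, start = hits$start,
                    end = hits$start + L, name = pattern, score = 0,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# E-value and significance for an observed number of matching windows.
motif_sig <- function(n_hit, n_windows, p_window, n_candidates_tested) {
  tail <- stats::pbinom(n_hit - 1, n_windows, p_window, lower.tail = FALSE)
  # work in logs so extreme enrichment does not underflow to sig = Inf
  log10_tail <- stats::pbinom(n_hit - 1, n_windows, p_window,
                              lower.tail = FALSE, log.p = TRUE) / log(10)
  e_value <- n_candidates_tested * tail
  list(e_value = e_value,
       sig_value = -(log10(n_candidates_tested) + log10_tail))
}

# Single-strand window count (each window is one both-orientation trial).
n_scan_windows <- function(sequences, motif_len) {
  sum(pmax(0L, Biostrings::width(sequences) - motif_len + 1L))
}

#' Motif statistics over a sequence set
#'
#' Computes the discovery-report summary for one motif: `count` (total
#' occurrences on both strands), `coverage` (fraction of sequences with at
#' least one occurrence on either strand) and `sig_value`
#' (-log10 E-value), where `E = n_candidates_tested * P(X >= x)` with
#' `X ~ Binomial(n_windows, p_window)`, `x` the number of distinct windows
#' matching the motif in either orientation, and `p_window` the
#' either-orientation match probability under the order-0 background. For a
#' motif whose expansion shares no word with its reverse complement's, `x`
#' equals `count`.
#'
#' @param pattern IUPAC motif string.
#' @param sequences Sequence set.
#' @param background Order-0 background (default: estimated from
#'   `sequences` via [background_model]).
#' @param n_candidates_tested Number of candidate motifs the search
#'   examined; 1 for a stand-alone evaluation.
#' @param algorithm Provenance tag stored in the result.
#' @return One-row data frame: `motif`, `count`, `sig_value`, `e_value`,
#'   `coverage`, `algorithm`.
#' @export
motif_stats <- function(pattern, sequences, background = NULL,
                        n_candidates_tested = 1, algorithm = "query") {
  pattern <- iupac_motif(pattern)
  sequences <- as_dna_set(sequences)
  assert_that(length(sequences) > 0L, "empty sequence set")
  assert_that(is.finite(n_candidates_tested) && n_candidates_tested >= 1,
              "n_candidates_tested must be >= 1")
  background <- background %||% background_model(sequences)
  cnt <- count_motif(pattern, sequences)
  n_win <- n_scan_windows(sequences, nchar(pattern))
  sig <- motif_sig(cnt$n_windows_hit, n_win, window_prob(pattern, background),
                   n_candidates_tested)
  data.frame(motif = pattern, count = cnt$count, sig_value = sig$sig_value,
             e_value = sig$e_value, coverage = cnt$covered / length(sequences),
             algorithm = algorithm)
}

# ---- word-table machinery for the search --------------------------------

# Count every exact L-mer on the PLUS strands only. Both-strand totals and
# distinct-window counts for any degenerate motif are then sums over its
# (forward / revcomp / union) expansion words -- provably identical to a
# full scan, and fast enough to drive the greedy search.
word_table <- function(seq_chars, L) {
  n <- nchar(seq_chars)
  keep <- n >= L
  if (!any(keep)) return(integer(0))
  words <- unlist(lapply(seq_chars[keep], function(s)
    substring(s, 1:(nchar(s) - L + 1L), L:nchar(s))), use.names = FALSE)
  words <- words[!grepl("[^ACGT]", words)]
  if (!length(words)) return(integer(0))
  tab <- table(words)
  stats::setNames(as.integer(tab), names(tab))
}

revcomp_words <- function(words) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
}

# A motif and its reverse complement have identical both-strand statistics
# and are one hypothesis; the canonical representative is the
# lexicographically smaller of the two patterns.
motif_canonical <- function(pattern) {
  rc <- iupac_revcomp(pattern)
  if (rc < pattern) rc else pattern
}

# Hash-backed lookup over a word table (repeated name-indexing into a large
# named vector re-hashes it every call; an environment does not).
word_lookup <- function(wt) {
  env <- new.env(hash = TRUE, size = max(1L, length(wt)), parent = emptyenv())
  nm <- names(wt)
  for (i in seq_along(wt)) assign(nm[i], wt[[i]], envir = env)
  function(words)
    sum(unlist(mget(words, envir = env, ifnotfound = 0L), use.names = FALSE))
}

# Degenerate-motif statistics from a plus-strand word table: both-strand
# occurrence total and number of distinct matching windows.
pattern_counts_from_table <- function(pattern, lookup) {
  fwd <- iupac_expand(pattern)
  rev <- iupac_expand(iupac_revcomp(pattern))
  c_fwd <- lookup(fwd)
  c_rev <- lookup(rev)
  shared <- intersect(fwd, rev)
  c_both <- if (length(shared)) lookup(shared) else 0L
  list(count = c_fwd + c_rev, n_windows_hit = c_fwd + c_rev - c_both)
}

# log10 word probabilities for a character vector of exact words (vectorized)
word_log10p <- function(words, background) {
  lp <- log10(background)
  n <- nchar(words[1L])
  out <- numeric(length(words))
  for (j in seq_len(n)) out <- out + lp[substring(words, j, j)]
  out
}

#' Discover overrepresented degenerate motifs
#'
#' Two-stage search over a promoter sequence set. Stage 1 (*beam*)
#' enumerates every exact word of each length occurring in the data (both
#' strands), scores all of them, and keeps the `beam_width` best per length
#' by significance. Stage 2 (*prism*) greedily generalizes each survivor
#' one position at a time to the IUPAC code that maximally increases the
#' significance, stopping when no single-position change helps or when
#' `max_degenerate_positions` positions are already degenerate. A motif and
#' its reverse complement carry identical both-strand statistics and count
#' as one hypothesis: results are collapsed to revcomp-equivalence classes
#' (reported in the lexicographically smaller orientation) and ranked by
#' significance, then coverage, then pattern. The search is deterministic.
#'
#' `n_candidates_tested` for the E-value is the total number of distinct
#' revcomp-equivalence classes of exact words enumerated across all lengths
#' in `length_range`.
#'
#' @param sequences Sequence set (>= 2 sequences).
#' @param background Order-0 background; default estimated from the input
#'   set itself. Supply a genome-style background set via
#'   [background_model] to mimic a genome-wide null.
#' @param length_range Two integers: motif lengths searched (default 5-10).
#' @param beam_width Exact words kept per length (default 50).
#' @param max_degenerate_positions Cap on degenerate positions per motif
#'   (default 4).
#' @param top Keep this many ranked motifs (default all).
#' @return Data frame of [motif_stats] rows, ranked; attribute
#'   `n_candidates_tested` records the multiple-testing multiplier.
#' @export
discover_motifs <- function(sequences, background = NULL,
                            length_range = c(5, 10), beam_width = 50,
                            max_degenerate_positions = 4, top = Inf) {
  sequences <- as_dna_set(sequences)
  assert_that(length(sequences) >= 2L, "need at least two sequences")
  assert_that(length(length_range) == 2L && length_range[1L] >= 2L &&
                length_range[1L] <= length_range[2L], "invalid length_range")
  background <- background %||% background_model(sequences)

  seq_chars <- as.character(sequences)
  lengths <- length_range[1L]:length_range[2L]
  tables <- lapply(lengths, function(L) word_table(seq_chars, L))
  names(tables) <- as.character(lengths)
  # candidate hypotheses per length: every exact word observed on either
  # strand, collapsed to revcomp-equivalence classes (w and rc(w) have
  # identical both-strand statistics)
  candidates <- lapply(tables, function(wt) {
    if (!length(wt)) return(character(0))
    words <- unique(c(names(wt), revcomp_words(names(wt))))
    unique(pmin(words, revcomp_words(words)))
  })
  n_cand <- sum(lengths(candidates))
  assert_that(n_cand > 0L, "sequences too short for the requested motif lengths")

  results <- list()
  for (L in lengths) {
    wt <- tables[[as.character(L)]]
    words <- candidates[[as.character(L)]]
    if (!length(words)) next
    n_win <- n_scan_windows(sequences, L)
    rc <- revcomp_words(words)
    palindromic <- words == rc
    c_fwd <- unname(wt[words]); c_fwd[is.na(c_fwd)] <- 0L
    c_rev <- unname(wt[rc]); c_rev[is.na(c_rev)] <- 0L
    n_hit <- ifelse(palindromic, c_fwd, c_fwd + c_rev)
    p_win <- 10^word_log10p(words, background) +
      ifelse(palindromic, 0, 10^word_log10p(rc, background))
    # vectorized exact-word significance
    log10_tail <- stats::pbinom(n_hit - 1L, n_win, p_win,
                                lower.tail = FALSE, log.p = TRUE) / log(10)
    sig <- -(log10(n_cand) + log10_tail)
    keep <- order(sig, decreasing = TRUE)[seq_len(min(beam_width, length(words)))]

    lookup <- word_lookup(wt)
    score_pattern <- function(pat) {
      cnt <- pattern_counts_from_table(pat, lookup)
      motif_sig(cnt$n_windows_hit, n_win, window_prob(pat, background),
                n_cand)$sig_value
    }
    for (i in keep) {
      seed_word <- words[i]
      results[[length(results) + 1L]] <-
        list(motif = seed_word, sig = sig[i], algorithm = "beam", L = L)
      refined <- prism_refine(seed_word, sig[i], score_pattern,
                              max_degenerate_positions)
      if (refined$motif != seed_word)
        results[[length(results) + 1L]] <-
          list(motif = refined$motif, sig = refined$sig, algorithm = "prism", L = L)
    }
  }

  for (i in seq_along(results))
    results[[i]]$motif <- motif_canonical(results[[i]]$motif)
  pats <- vapply(results, `[[`, "", "motif")
  dup <- duplicated(pats)
  results <- results[!dup]; pats <- pats[!dup]
  stats <- do.call(rbind, lapply(results, function(r) {
    s <- motif_stats(r$motif, sequences, background, n_candidates_tested = n_cand,
                     algorithm = r$algorithm)
    s
  }))
  o <- order(-stats$sig_value, -stats$coverage, stats$motif)
  stats <- stats[o, , drop = FALSE]
  rownames(stats) <- NULL
  if (is.finite(top)) stats <- utils::head(stats, top)
  attr(stats, "n_candidates_tested") <- n_cand
  stats
}

# Greedy single-position degeneration: at each step try every IUPAC code
# strictly containing the current base set at every position; accept the
# change with the largest significance gain.
prism_refine <- function(word, sig0, score_pattern, max_degenerate_positions) {
  current <- strsplit(word, "", fixed = TRUE)[[1L]]
  best_sig <- sig0
  repeat {
    n_degen <- sum(vapply(IUPAC_SETS[current], length, 1L) > 1L)
    if (n_degen >= max_degenerate_positions) break
    step_best <- NULL
    for (pos in seq_along(current)) {
      cur_set <- IUPAC_SETS[[current[pos]]]
      for (code in names(IUPAC_SETS)) {
        sup <- IUPAC_SETS[[code]]
        if (length(sup) <= length(cur_set) || !all(cur_set %in% sup)) next
        cand <- current; cand[pos] <- code
        s <- score_pattern(paste(cand, collapse = ""))
        if (s > best_sig + 1e-12 && (is.null(step_best) || s > step_best$sig)) {
          step_best <- list(chars = cand, sig = s)
        }
      }
    }
    if (is.null(step_best)) break
    current <- step_best$chars
    best_sig <- step_best$sig
  }
  list(motif = paste(current, collapse = ""), sig = best_sig)
}

#' Evaluate a query motif over one or more sequence sets
#'
#' Applies [motif_stats] per set, e.g. to ask whether a discovered motif is
#' overrepresented in random-gene control sets or in later first-presence
#' groups (where a negative significance is the expected outcome).
#'
#' @param pattern IUPAC motif string.
#' @param sequence_sets A single sequence set or a named list of sets.
#' @param background Optional shared background; default per-set.
#' @param n_candidates_tested Multiple-testing multiplier; default mirrors
#'   the discovery configuration by counting the distinct exact words of
#'   lengths `length_range` present in each set.
#' @param length_range Used only for the default `n_candidates_tested`.
#' @return Data frame, one [motif_stats] row per set, with a `set` column.
#' @export
evaluate_query <- function(pattern, sequence_sets, background = NULL,
                           n_candidates_tested = NULL, length_range = c(5, 10)) {
  if (!is.list(sequence_sets)) sequence_sets <- list(set1 = sequence_sets)
  assert_that(length(sequence_sets) > 0L, "no sequence sets supplied")
  if (is.null(names(sequence_sets)))
    names(sequence_sets) <- sprintf("set%d", seq_along(sequence_sets))
  out <- lapply(names(sequence_sets), function(nm) {
    seqs <- as_dna_set(sequence_sets[[nm]])
    assert_that(length(seqs) > 0L, "empty sequence set: ", nm)
    n_cand <- n_candidates_tested
    if (is.null(n_cand)) {
      sc <- as.character(seqs)
      n_cand <- sum(vapply(length_range[1L]:length_range[2L], function(L) {
        wt <- word_table(sc, L)
        if (!length(wt)) return(0L)
        words <- unique(c(names(wt), revcomp_words(names(wt))))
        length(unique(pmin(words, revcomp_words(words))))
      }, 1L))
    }
    cbind(data.frame(set = nm),
          motif_stats(pattern, seqs, background, n_candidates_tested = n_cand))
  })
  do.call(rbind, out)
}

#' Write a ranked motif table as TSV
#'
#' Columns mirror the discovery report style: Motif, Count, Sig Value,
#' Coverage, Algorithm.
#'
#' @param stats Data frame from [discover_motifs] or [motif_stats].
#' @param path Output path.
#' @export
write_motif_table <- function(stats, path) {
  out <- data.frame(motif = stats$motif, count = stats$count,
                    sig_value = stats$sig_value, coverage = stats$coverage,
                    algorithm = stats$algorithm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
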