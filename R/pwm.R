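# Position weight matrices: construction from hits or consensus strings,
# ungapped alignment with per-column Pearson correlation, and an empirical
# permutation E-value for cross-species motif homology assessment.

PWM_BASES <- c("A", "C", "G", "T")

#' Construct a PWM object
#'
#' @param matrix Numeric 4 x L matrix of base probabilities, rows in the
#'   fixed order A, C, G, T; every column must sum to 1.
#' @param n_sites Number of sites the matrix was built from (provenance).
#' @param name Motif name.
#' @return An object of class `pwm`.
#' @export
pwm <- function(matrix, n_sites = NA_integer_, name = "motif") {
  matrix <- as.matrix(matrix)
  assert_that(nrow(matrix) == 4L, "PWM must have 4 rows (A, C, G, T)")
  assert_that(ncol(matrix) >= 1L, "PWM must have at least one column")
  assert_that(all(is.finite(matrix)) && all(matrix >= 0), "PWM entries must be >= 0")
  assert_that(all(abs(colSums(matrix) - 1) < 1e-9), "PWM columns must sum to 1")
  dimnames(matrix) <- list(PWM_BASES, NULL)
  structure(list(matrix = matrix, n_sites = n_sites, name = name), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "-", ncol(x$matrix), "columns,",
      if (is.na(x$n_sites)) "consensus-derived" else paste(x$n_sites, "sites"), "\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Build a PWM from motif hits in sequences
#'
#' Stacks the hit substrings (minus-strand hits are reverse-complemented
#' first) and converts per-column base counts to probabilities with a
#' pseudocount: `(count_b + pc) / (n_sites + 4 pc)` (with the default
#' `pc = 0.25` the denominator is `n_sites + 1`).
#'
#' @param hits Data frame from [scan_motif] (`seq_id`, `start`, `strand`).
#' @param sequences The scanned sequence set.
#' @param motif_length Site length; inferred from `pattern` if given.
#' @param pseudocount Smoothing constant per base (default 0.25).
#' @param name Motif name for the resulting PWM.
#' @return A [pwm] with `n_sites = nrow(hits)`.
#' @export
pwm_from_hits <- function(hits, sequences, motif_length, pseudocount = 0.25,
                          name = "motif") {
  assert_that(nrow(hits) >= 1L, "need at least one hit")
  assert_that(is.finite(pseudocount) && pseudocount >= 0,
              "pseudocount must be >= 0")
  sequences <- as_dna_set(sequences)
  idx <- match(hits$seq_id, names(sequences))
  assert_that(!anyNA(idx), "hit(s) refer to unknown sequence ids")
  sites <- substring(as.character(sequences)[idx], hits$start + 1L,
                     hits$start + motif_length)
  assert_that(all(nchar(sites) == motif_length), "hit(s) extend past sequence end")
  rc <- hits$strand == "-"
  if (any(rc))
    sites[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(sites[rc])))
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sites))[PWM_BASES, ,
                                                                      drop = FALSE]
  n <- length(sites)
  pwm((mat + pseudocount) / (n + 4 * pseudocount), n_sites = n, name = name)
}

#' Build a PWM from a degenerate consensus
#'
#' Each column is uniform over the bases its IUPAC code allows -- the
#' stand-in used when only a printed consensus (e.g. `TAGGTAG`) is
#' available rather than observed sites.
#'
#' @param pattern IUPAC motif string.
#' @param name Motif name (defaults to the pattern).
#' @return A [pwm] with `n_sites = NA`.
#' @export
pwm_from_iupac <- function(pattern, name = pattern) {
  pattern <- iupac_motif(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  mat <- vapply(chars, function(ch) {
    v <- stats::setNames(numeric(4L), PWM_BASES)
    v[IUPAC_SETS[[ch]]] <- 1 / length(IUPAC_SETS[[ch]])
    v
  }, numeric(4L))
  pwm(mat, name = name)
}

#' Reverse-complement a PWM
#'
#' Column `i` maps to column `L - i + 1` and the base vector
#' `(a, c, g, t)` maps to `(t, g, c, a)`.
#'
#' @param x A [pwm].
#' @return The reverse-complemented [pwm].
#' @export
pwm_revcomp <- function(x) {
  assert_that(inherits(x, "pwm"), "x must be a pwm")
  m <- x$matrix[4:1, rev(seq_len(ncol(x$matrix))), drop = FALSE]
  pwm(m, n_sites = x$n_sites, name = paste0(x$name, "_rc"))
}

# Columns centered and scaled to unit norm so the mean per-column Pearson
# correlation of an overlap is a mean of dot products. Zero-variance
# columns (e.g. a uniform N column) get a zero vector: their PCC is 0.
normalize_columns <- function(m) {
  centered <- sweep(m, 2L, colMeans(m))
  norms <- sqrt(colSums(centered^2))
  ok <- norms > 1e-12
  centered[, ok] <- sweep(centered[, ok, drop = FALSE], 2L, norms[ok], "/")
  centered[, !ok] <- 0
  centered
}

#' Align two PWMs (ungapped, both orientations)
#'
#' Slides the target across the query over every offset with at least
#' `min_overlap` overlapping columns, in both orientations (the target
#' reverse-complemented for the second), scoring each overlap as the mean
#' Pearson correlation between paired probability 4-vectors. Returns the
#' best alignment; ties break toward larger overlap, then smaller
#' `|offset|`, then forward orientation. `offset` is the position of the
#' target's first column relative to the query's first column.
#'
#' @param q,t Query and target [pwm] objects.
#' @param min_overlap Minimum overlapping columns (default 4).
#' @param metric `"pcc"` (default, score in `[-1, 1]`) or `"ssd"`
#'   (negative mean sum of squared differences).
#' @return List of class `pwm_alignment`: `offset`, `orientation`
#'   (`"forward"`/`"revcomp"`), `n_overlap`, `score`, plus the motif names.
#' @export
align_pwms <- function(q, t, min_overlap = 4, metric = c("pcc", "ssd")) {
  metric <- match.arg(metric)
  assert_that(inherits(q, "pwm") && inherits(t, "pwm"), "q and t must be pwm objects")
  Lq <- ncol(q$matrix); Lt <- ncol(t$matrix)
  assert_that(min_overlap >= 1, "min_overlap must be >= 1")
  assert_that(Lq >= min_overlap && Lt >= min_overlap,
              "PWM shorter than min_overlap")
  qn <- if (metric == "pcc") normalize_columns(q$matrix) else q$matrix
  best <- NULL
  for (orientation in c("forward", "revcomp")) {
    tm <- if (orientation == "forward") t$matrix else pwm_revcomp(t)$matrix
    tn <- if (metric == "pcc") normalize_columns(tm) else tm
    for (offset in seq(-(Lt - min_overlap), Lq - min_overlap)) {
      qi <- max(1L, 1L + offset):min(Lq, Lt + offset)
      ti <- qi - offset
      n_overlap <- length(qi)
      if (n_overlap < min_overlap) next
      score <- if (metric == "pcc")
        mean(colSums(qn[, qi, drop = FALSE] * tn[, ti, drop = FALSE]))
      else
        -mean(colSums((qn[, qi, drop = FALSE] - tn[, ti, drop = FALSE])^2))
      cand <- list(query = q$name, target = t$name, offset = offset,
                   orientation = orientation, n_overlap = n_overlap,
                   score = score)
      if (is.null(best) || better_alignment(cand, best)) best <- cand
    }
  }
  structure(best, class = "pwm_alignment")
}

better_alignment <- function(a, b) {
  if (abs(a$score - b$score) > 1e-12) return(a$score > b$score)
  if (a$n_overlap != b$n_overlap) return(a$n_overlap > b$n_overlap)
  if (abs(a$offset) != abs(b$offset)) return(abs(a$offset) < abs(b$offset))
  a$orientation == "forward" && b$orientation != "forward"
}

#' @export
print.pwm_alignment <- function(x, ...) {
  cat(sprintf("%s vs %s: score %.4f, offset %+d, %s, %d columns",
              x$query, x$target, x$score, x$offset, x$orientation, x$n_overlap))
  if (!is.null(x$e_value)) cat(sprintf(", E = %.3g", x$e_value))
  cat("\n")
  invisible(x)
}

#' Empirical permutation E-value for a PWM alignment
#'
#' Builds a null distribution by repeatedly shuffling the target's columns
#' and, independently within each column, its base order, re-aligning the
#' query each time. The empirical p-value is
#' `(1 + #\{null >= observed\}) / (n_null + 1)` and the E-value is
#' `n_null * p`: the expected number of equal-or-better scores among the
#' null comparisons. Deterministic given `seed`. This is the package's own
#' calibration; it is not comparable in absolute value to database-
#' calibrated E-values.
#'
#' @param q,t Query and target [pwm] objects.
#' @param n_null Number of null permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @param min_overlap,metric Passed to [align_pwms].
#' @return The observed [align_pwms] result with `e_value`, `p_empirical`
#'   and `n_null` fields added.
#' @export
pwm_alignment_evalue <- function(q, t, n_null = 10000, seed = 1,
                                 min_overlap = 4, metric = "pcc") {
  assert_that(is_count_scalar(n_null) && n_null >= 1, "n_null must be >= 1")
  obs <- align_pwms(q, t, min_overlap = min_overlap, metric = metric)
  tm <- t$matrix
  null_scores <- with_seed(derive_seed(seed, "pwm_null"), {
    vapply(seq_len(n_null), function(i) {
      perm <- tm[, sample.int(ncol(tm)), drop = FALSE]
      for (j in seq_len(ncol(perm))) perm[, j] <- perm[sample.int(4L), j]
      align_pwms(q, pwm(perm, name = "null"), min_overlap = min_overlap,
                 metric = metric)$score
    }, 0)
  })
  p_emp <- (1 + sum(null_scores >= obs$score - 1e-12)) / (n_null + 1)
  obs$p_empirical <- p_emp
  obs$e_value <- n_null * p_emp
  obs$n_null <- n_null
  obs
}

#' Read / write PWMs in minimal MEME motif format
#'
#' Writes a version-4 MEME text file (alphabet ACGT, one
#' `letter-probability matrix` block per motif). `read_meme` returns a
#' named list of [pwm] objects. Note MEME stores positions as rows; the
#' in-memory representation is transposed (bases as rows).
#'
#' @param pwms A [pwm] or list of them.
#' @param path File path.
#' @return `write_meme` returns `path` invisibly; `read_meme` a named list
#'   of [pwm] objects.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    nsites <- if (is.na(p$n_sites)) 20L else p$n_sites
    writeLines(c(paste("MOTIF", p$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         ncol(p$matrix), nsites)), con)
    utils::write.table(format(t(p$matrix), digits = 6), con, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  assert_that(file.exists(path), "MEME file not found: ", path)
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\s+", lines)
  assert_that(length(motif_at) > 0L, "no MOTIF blocks in ", path)
  out <- list()
  for (i in motif_at) {
    name <- sub("^MOTIF\\s+", "", lines[i])
    name <- strsplit(trimws(name), "\\s+")[[1L]][1L]
    hdr <- i + which(grepl("^letter-probability matrix", lines[(i + 1):length(lines)]))[1L]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    ns <- if (grepl("nsites=", lines[hdr]))
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[hdr])) else NA_integer_
    rows <- lines[(hdr + 1):(hdr + w)]
    m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(x) as.numeric(x[1:4]), numeric(4L)))
    mat <- t(m)
    mat <- sweep(mat, 2L, colSums(mat), "/") # renormalize printed precision
    out[[name]] <- pwm(mat, n_sites = ns, name = name)
  }
  out
}

#' Write an alignment report TSV
#'
#' @param alignments A `pwm_alignment` or list of them.
#' @param path Output path.
#' @export
write_alignment_report <- function(alignments, path) {
  if (inherits(alignments, "pwm_alignment")) alignments <- list(alignments)
  rows <- lapply(alignments, function(a)
    data.frame(query = a$query, target = a$target, offset = a$offset,
               orientation = a$orientation, n_overlap = a$n_overlap,
               score = a$score, e_value = a$e_value %||% NA_real_))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
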