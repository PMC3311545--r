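# IUPAC degenerate nucleotide codes: expansion, complementation, and the
# per-position base sets used throughout motif discovery and PWM construction.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# code string for a sorted base set, e.g. c("A","G") -> "R"
IUPAC_FROM_SET <- local({
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(names(IUPAC_SETS), keys)
})

iupac_code_for <- function(bases) {
  IUPAC_FROM_SET[[paste(sort(unique(bases)), collapse = "")]]
}

#' Validate an IUPAC motif pattern
#'
#' @param pattern Character scalar over the 15 IUPAC nucleotide codes
#'   (`A C G T R Y S W K M B D H V N`), e.g. `"VBRGGTA"`.
#' @return The pattern, uppercased, invisibly usable downstream.
#' @export
iupac_motif <- function(pattern) {
  assert_that(is.character(pattern) && length(pattern) == 1L && !is.na(pattern),
              "motif pattern must be a single string")
  pattern <- toupper(pattern)
  assert_that(nchar(pattern) > 0L, "motif pattern must be non-empty")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  assert_that(length(bad) == 0L,
              "invalid IUPAC code(s) in motif: ", paste(unique(bad), collapse = ", "))
  pattern
}

#' Expand a degenerate motif into its concrete words
#'
#' The expansion-set size is the product of per-position degeneracies;
#' `VBRGGTA` expands to 3 x 3 x 2 = 18 words.
#'
#' @param pattern IUPAC motif string.
#' @return Character vector of all concrete DNA words matching the pattern.
#' @examples
#' length(iupac_expand("VBRGGTA")) # 18
#' @export
iupac_expand <- function(pattern) {
  pattern <- iupac_motif(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  sets <- IUPAC_SETS[chars]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  words <- do.call(paste0, rev(grid))
  sort(words)
}

#' Reverse-complement a degenerate motif
#'
#' Complementation maps each code to the code of the complemented base set
#' (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H; S, W and N are self-complementary),
#' then reverses; e.g. the complement of `VBRGGTA` is `TACCYVB`.
#'
#' @param pattern IUPAC motif string.
#' @return The reverse-complement IUPAC motif string.
#' @export
iupac_revcomp <- function(pattern) {
  pattern <- iupac_motif(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

# Degeneracy per position (vector of set sizes).
iupac_degeneracy <- function(pattern) {
  chars <- strsplit(iupac_motif(pattern), "", fixed = TRUE)[[1L]]
  vapply(IUPAC_SETS[chars], length, 1L)
}

# Pick one concrete expansion uniformly at random (used by the simulator).
iupac_sample_word <- function(pattern) {
  chars <- strsplit(iupac_motif(pattern), "", fixed = TRUE)[[1L]]
  paste(vapply(IUPAC_SETS[chars], function(s) s[sample.int(length(s), 1L)], ""),
        collapse = "")
}
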