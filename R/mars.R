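# MA-plot-based random-sampling (MARS) significance test for a pair of
# unreplicated count libraries, and Storey q-values.
#
# Model: under H0 the two raw counts are binomial draws with a common
# sampling proportion p from libraries of size n1 and n2. With
# X = log2(k1 + pc), Y = log2(k2 + pc), M = X - Y and A = (X + Y)/2, a
# delta-method normal approximation gives (M, A) a bivariate normal null;
# the test refers M to its conditional mean and variance given A.

#' MARS test for a pair of unreplicated counts
#'
#' Tests whether a transcript's count differs between two libraries more than
#' expected under a common binomial sampling proportion. All arguments are
#' vectorized over transcripts.
#'
#' The null moments come from the delta method applied to the
#' *pseudocounted* statistic: the common sampling proportion is the pooled
#' estimate `p_hat = (k1 + k2)/(n1 + n2)` (clamped to (0, 1); the
#' `saturated` flag marks the upper clamp), and
#' `E(X) = log2(n1 p + c)`, `Var(X) = n1 p (1 - p) / ((n1 p + c)^2 ln^2 2)`
#' with the analogous terms for Y. As `c -> 0` these reduce to the
#' classical `p_hat = 2^A / sqrt(n1 n2)`, `mu = log2(n p)`,
#' `var = (1 - p)/(n p ln^2 2)`; keeping `c` in the moments preserves
#' type-I calibration at small counts and unequal library sizes, where the
#' classical form biases E(M). The deviate refers M to the plug-in
#' conditional mean, `z = |M - E(M|A)| / sqrt(var_null)` with `var_null`
#' the delta-method variance of the full plug-in statistic (see the
#' methods vignette), and `p = 2 (1 - pnorm(z))`.
#'
#' @param k1,k2 Non-negative raw counts for the two libraries.
#' @param n1,n2 Positive library sizes (total mapped hit counts).
#' @param pseudocount Added to both counts before taking logs so that zero
#'   counts (the rule rather than the exception for early zygotic
#'   candidates in the 0-2 hr library) stay finite. Default 1.
#' @return A data frame with one row per test: pseudocounted `k1`, `k2`,
#'   `m`, `a`, the conditional null mean `m_expected` = E(M|A), the null
#'   variance `var_null` of the plug-in statistic,
#'   `m_shift` = M - E(M|A) (positive means k1 above its null share),
#'   `z`, `p_value` and the `saturated` clamp flag.
#' @examples
#' mars_test(100, 100, 1e6, 1e6)$p_value # 1: symmetric null
#' @export
mars_test <- function(k1, k2, n1, n2, pseudocount = 1) {
  n <- max(length(k1), length(k2))
  k1 <- rep_len(as.numeric(k1), n); k2 <- rep_len(as.numeric(k2), n)
  n1 <- rep_len(as.numeric(n1), n); n2 <- rep_len(as.numeric(n2), n)
  assert_that(all(is.finite(c(k1, k2))) && all(c(k1, k2) >= 0),
              "counts must be finite and non-negative")
  assert_that(all(is.finite(c(n1, n2))) && all(c(n1, n2) > 0),
              "library sizes must be positive")
  assert_that(is.finite(pseudocount) && pseudocount > 0,
              "pseudocount must be positive")

  k1p <- k1 + pseudocount
  k2p <- k2 + pseudocount
  x <- log2(k1p); y <- log2(k2p)
  m <- x - y
  a <- (x + y) / 2

  # pooled MLE of the common sampling proportion under H0, floored at the
  # pseudocount's own share so the all-zero case stays well-conditioned.
  # (Estimating p from A instead would force E(A) = a identically, killing
  # the regression term of E(M|A) while its variance reduction is still
  # subtracted -- an anticonservative null for unequal library sizes.)
  c0 <- pseudocount
  p_hat <- (k1 + k2) / (n1 + n2)
  saturated <- p_hat >= 1
  p_hat <- pmin(pmax(p_hat, c0 / (n1 + n2)), 1 - 1e-12)

  # delta-method moments of log2(k + c) for k ~ Binomial(n, p); the
  # pseudocount enters the mean and damps the variance, so the null stays
  # calibrated down to small expected counts (c -> 0 recovers the
  # classical  mu = log2(n p), var = (1 - p) / (n p ln^2 2))
  ln2 <- log(2)
  u_p <- 1 / ((n1 * p_hat + c0) * ln2)       # d log2(k1 + c) / d k1
  v_p <- 1 / ((n2 * p_hat + c0) * ln2)
  s1 <- n1 * p_hat * (1 - p_hat)             # Var(k1), Var(k2)
  s2 <- n2 * p_hat * (1 - p_hat)
  var_x <- s1 * u_p^2
  var_y <- s2 * v_p^2
  mu_x <- log2(n1 * p_hat + c0); mu_y <- log2(n2 * p_hat + c0)

  e_m <- mu_x - mu_y
  e_a <- (mu_x + mu_y) / 2
  cond <- mars_conditional(var_x, var_y, e_m, e_a, a)
  m_shift <- m - cond$mean

  # null variance of the *plug-in* statistic m - E-hat(M | a): because
  # e_m, e_a and the regression pivot all depend on p_hat = (k1+k2)/N,
  # the naive Var(M|a) is biased (anticonservative for p_hat-from-A,
  # conservative for pooled p_hat); propagate (k1, k2) through the whole
  # statistic instead. For n1 = n2 this collapses to Var(M).
  beta <- 2 * (var_x - var_y) / (var_x + var_y)
  U <- n1 / (n1 * p_hat + c0)
  V <- n2 / (n2 * p_hat + c0)
  g_m <- (U - V) / ln2                       # d e_m / d p
  g_a <- (U + V) / (2 * ln2)                 # d e_a / d p
  drift <- (g_m - beta * g_a) / (n1 + n2)
  c1 <- u_p * (1 - beta / 2) - drift
  c2 <- -v_p * (1 + beta / 2) - drift
  var_null <- c1^2 * s1 + c2^2 * s2

  z <- abs(m_shift) / sqrt(var_null)
  p_value <- 2 * stats::pnorm(z, lower.tail = FALSE)

  data.frame(k1 = k1p, k2 = k2p, m = m, a = a,
             m_expected = cond$mean, var_null = var_null, m_shift = m_shift,
             z = z, p_value = p_value, saturated = saturated)
}

# Closed-form conditional moments of M given A = a for the bivariate-normal
# null of (M, A) induced by independent X ~ N(mu_x, var_x), Y ~ N(mu_y,
# var_y) with M = X - Y, A = (X + Y)/2. Vectorized over all arguments.
mars_conditional <- function(var_x, var_y, e_m, e_a, a) {
  var_m <- var_x + var_y
  var_a <- var_m / 4
  cov_ma <- (var_x - var_y) / 2
  list(mean = e_m + (cov_ma / var_a) * (a - e_a),
       var = var_m - cov_ma^2 / var_a)
}

#' MARS table for one time-bin pair of a count matrix
#'
#' Runs [mars_test] for every transcript between two time bins and attaches
#' Storey q-values. The later bin is placed in the `k1` slot, so
#' `m = log2(later/earlier)` (after pseudocounting) and a positive `m_shift`
#' means expression *increased* at the later bin relative to its null share
#' -- the direction the early-zygotic filter cares about.
#'
#' @param x A [tc_counts] object.
#' @param bin_pair Length-2 vector of bin indices (1-4) or names
#'   (`"h0_2"`, ...), earlier first. Default compares 0-2 hr vs 2-4 hr.
#' @param pseudocount Passed to [mars_test].
#' @return Data frame: `transcript_id`, the [mars_test] columns, and
#'   `q_value`; attribute `bin_pair` records the (earlier, later) bin names.
#' @export
mars_table <- function(x, bin_pair = c("h0_2", "h2_4"), pseudocount = 1) {
  assert_that(inherits(x, "tc_counts"), "x must be a tc_counts object")
  assert_that(length(bin_pair) == 2L, "bin_pair must have two entries")
  if (is.numeric(bin_pair)) bin_pair <- BIN_NAMES[bin_pair]
  assert_that(all(bin_pair %in% BIN_NAMES),
              "unknown bin(s): ", paste(bin_pair, collapse = ", "))
  assert_that(bin_pair[1L] != bin_pair[2L], "bin_pair entries must differ")
  earlier <- bin_pair[1L]; later <- bin_pair[2L]
  res <- mars_test(k1 = x$counts[, later], k2 = x$counts[, earlier],
                   n1 = x$library_sizes[[later]], n2 = x$library_sizes[[earlier]],
                   pseudocount = pseudocount)
  out <- cbind(data.frame(transcript_id = x$transcript_ids), res)
  out$q_value <- if (nrow(out) > 0L) compute_qvalues(out$p_value) else numeric(0)
  attr(out, "bin_pair") <- c(earlier, later)
  out
}

#' Storey q-values
#'
#' Estimates the null proportion as
#' `pi0 = #\{p > lambda\} / (m (1 - lambda))` with `lambda = 0.5`, clamped to
#' `[1/m, 1]`, then assigns `q(p_(i)) = min_(j >= i) pi0 m p_(j) / j` over
#' the sorted p-values (capped at 1). q-values are monotone in p.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param lambda Tuning point for the pi0 estimate; fixed default 0.5
#'   (no spline -- a single unreplicated library pair does not support one).
#' @return Numeric vector of q-values, same order as the input.
#' @export
compute_qvalues <- function(p_values, lambda = 0.5) {
  assert_that(length(p_values) > 0L, "empty p-value vector")
  assert_that(all(is.finite(p_values)) && all(p_values >= 0) && all(p_values <= 1),
              "p-values must lie in [0, 1]")
  assert_that(is.finite(lambda) && lambda > 0 && lambda < 1,
              "lambda must lie in (0, 1)")
  m <- length(p_values)
  pi0 <- sum(p_values > lambda) / (m * (1 - lambda))
  pi0 <- min(max(pi0, 1 / m), 1)
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(pi0 * m * p_values[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Write a MARS table as TSV
#'
#' Columns: transcript_id, k1, k2, m, a, z, p_value, q_value, plus one
#' boolean significance column per threshold.
#'
#' @param tab Result of [mars_table].
#' @param path Output path.
#' @param thresholds Raw p-value thresholds for the indicator columns.
#' @export
write_mars_table <- function(tab, path, thresholds = c(0.001, 0.05)) {
  out <- tab[c("transcript_id", "k1", "k2", "m", "a", "z", "p_value", "q_value")]
  for (th in thresholds)
    out[[paste0("significant_", th)]] <- tab$p_value < th & tab$m_shift > 0
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
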