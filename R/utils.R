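# Internal helpers shared across modules.

BIN_NAMES <- c("h0_2", "h2_4", "h4_8", "h8_12")
BIN_LABELS <- c("0-2", "2-4", "4-8", "8-12")

abort <- function(..., class = "ezgkit_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) abort(..., class = "ezgkit_validation_error")
  invisible(TRUE)
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

# Evaluate `expr` under a temporary RNG state seeded from `seed`; the caller's
# RNG stream is restored afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, expr) {
  assert_that(is_count_scalar(seed), "seed must be a single non-negative integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific seed from the single global seed, kept below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(counts = 0L, upstream = 1L, annotations = 2L, pwm_null = 3L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

`%||%` <- function(x, y) if (is.null(x)) y else x
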