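# Small internal helpers shared across the package.

unit_norm <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(v)
  v / nv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic integer seed stream; always in [1, 2^31 - 2] so it is a
# valid value for set.seed() on 32-bit integers.
derive_seed <- function(seed, i, stream = 0L) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                as.numeric(i) * 7919 +
                as.numeric(stream) * 104729) %% 2147483646 + 1)
}

# Pearson correlation that returns NA instead of erroring on a
# zero-variance argument; direct formula, cheap on short vectors.
safe_cor <- function(a, b) {
  da <- a - mean(a)
  db <- b - mean(b)
  va <- sum(da * da)
  vb <- sum(db * db)
  if (va == 0 || vb == 0) return(NA_real_)
  sum(da * db) / sqrt(va * vb)
}

n_nonzero <- function(v) sum(v != 0)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
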