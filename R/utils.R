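# Internal helpers: seed substreams, validation, small numerics.

# Deterministic substream seed derived from a root seed and a sequence of
# integer/character ids. Kept below 2^31 - 1 so set.seed() accepts it.
substream_seed <- function(seed, ...) {
  ids <- list(...)
  val <- as.numeric(seed) %% 2147483647
  for (id in ids) {
    if (is.character(id)) id <- sum(utf8ToInt(id))
    val <- (val * 69069 + as.numeric(id) + 1) %% 2147483647
  }
  as.integer(val)
}

# Run code under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == round(x)
}

# Column standard deviations with the n-1 denominator, without forming
# per-column copies. x: matrix (rows = time).
col_sds <- function(x) {
  n <- nrow(x)
  assert_that(n >= 2, "need at least 2 rows to compute a standard deviation")
  mu <- colMeans(x)
  ss <- colSums(x^2) - n * mu^2
  ss[ss < 0] <- 0 # numerical guard
  sqrt(ss / (n - 1))
}

# Lag-1 sample autocorrelation pooled over columns of a residual matrix.
pooled_lag1 <- function(e) {
  t_n <- nrow(e)
  num <- sum(e[-1, , drop = FALSE] * e[-t_n, , drop = FALSE])
  den <- sum(e^2)
  if (den <= 0) abort("residuals have zero variance; lag-1 autocorrelation undefined")
  num / den
}
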