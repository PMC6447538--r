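# Internal helpers shared across modules.

# Derive a reproducible substream seed from a global seed and a stream name.
# Adding a new named stream never shifts the draws of existing streams.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483587)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Spearman correlation p-value via the t approximation (n >= 4).
spearman_p <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  ok <- is.finite(rho) & n > 2
  r <- pmin(pmax(rho[ok], -1 + 1e-12), 1 - 1e-12)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p[ok] <- 2 * pt(-abs(tval), df = n - 2)
  p
}

# Row-wise ranks of a matrix (average ties), returned as a matrix.
row_ranks <- function(x) {
  t(apply(x, 1L, rank, ties.method = "average"))
}

# Standardize rows to zero mean / unit norm so that tcrossprod gives
# correlations; constant rows become NA rows.
standardize_rows <- function(x) {
  ctr <- x - rowMeans(x)
  ss <- sqrt(rowSums(ctr^2))
  ss[ss == 0] <- NA_real_
  ctr / ss
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
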