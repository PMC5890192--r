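# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# `seed = NULL` means "use the ambient RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic sub-stream seed, kept inside 32-bit integer range.
child_seed <- function(seed, index) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.double(seed) * 48271 + as.double(index)) %% 2147483629)
}

# Column variances with denominator `n` (population) or `n - 1` (sample).
col_vars <- function(x, ddof = 0L) {
  n <- nrow(x)
  ctr <- sweep(x, 2L, colMeans(x))
  colSums(ctr^2) / (n - ddof)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Pearson correlation of each row of `m` with vector `y`; rows with zero
# variance give NA.
row_correlations <- function(m, y) {
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  mc <- m - rowMeans(m)
  sm <- sqrt(rowSums(mc^2))
  r <- as.vector(mc %*% yc) / (sm * sy)
  r[sm == 0 | sy == 0] <- NA_real_
  unname(r)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
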