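# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes through this, so identical
# seeds give byte-identical results without disturbing the session RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of sub-seeds from one base seed, kept within 32-bit range.
derive_seeds <- function(base_seed, n, stream = 0L) {
  (as.integer(base_seed) %% 1000003L) * 2011L + stream * 1000003L + seq_len(n)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Pearson/Spearman that tolerate degenerate inputs (constant vectors -> NA
# with no warning noise).
safe_cor <- function(x, y, method = "pearson") {
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
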