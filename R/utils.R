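## Internal helpers shared across modules.

# Evaluate expr under a local RNG state seeded with `seed` (NULL = leave
# the global stream alone).  Restores .Random.seed afterwards so library
# code never perturbs a caller's stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Deterministic derived seed for a named analysis stage (kept < 2^31).
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 2017L + h %% 100003L
}

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logSumExp over the columns of a matrix (rows = categories,
# columns = sites): returns a vector over columns.
.colLogSumExp <- function(mat) {
  m <- apply(mat, 2L, max)
  m + log(colSums(exp(sweep(mat, 2L, m, "-"))))
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
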