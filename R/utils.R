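# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child seed for stage `k` of a run seeded with `seed`;
# stays inside the 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 48271 + 99991 * as.numeric(k)) %%
               2147483629)
}

# Coerce a vector or matrix to an N x k numeric block; NULL -> 0 columns.
as_block <- function(x, n = NULL) {
  if (is.null(x)) {
    stopifnot(!is.null(n))
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || !all(is.finite(x)))
    stop("realization blocks must be finite and free of missing values")
  x
}

stop_if_not_scalar_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min ||
      x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
}
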