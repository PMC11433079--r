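# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Stable 31-bit string hash (polynomial rolling hash) used to derive
# per-image substreams from one top-level seed; invariant to sample order.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
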