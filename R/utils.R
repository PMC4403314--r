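# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# derive a stream of sub-seeds below 2^31 from a master seed
derive_seeds <- function(seed, n, salt = 0L) {
  (as.numeric(seed) * 7919 + salt * 104729 + seq_len(n) * 2654435761) %% 2147483647
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
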