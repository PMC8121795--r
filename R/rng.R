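# Seed hygiene: run seeded code without clobbering the caller's RNG state.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.local_rng <- function(seed) {
  list(sample_order = function(n) with_seed(seed, sample.int(n)))
}

# Deterministic 31-bit hash of a string (for per-word embedding jitter).
.string_hash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}
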