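# Seed handling.
#
# Every generator takes an integer seed; per-slide and per-rater seeds are
# derived from the master seed by a stable string hash so that results do
# not depend on iteration order. Stochastic oracles (classifier, segmenter)
# own a private RNG stream that persists across calls without disturbing
# the caller's RNG state.

# Stable 31-bit hash of (master seed, identifier string).
derive_seed <- function(master, id) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 131 + ch) %% m
  # mix with the master seed; all intermediates stay below 2^53
  as.integer(((h * 31 + (as.numeric(master) %% m)) * 69069 + 1) %% m)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# A persistent RNG stream: an environment holding a saved .Random.seed.
new_rng_stream <- function(seed) {
  stream <- new.env(parent = emptyenv())
  with_seed(seed, stream$state <- get(".Random.seed", envir = globalenv()))
  stream
}

# Evaluate `expr` using the stream's state; save the advanced state back.
stream_eval <- function(stream, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  assign(".Random.seed", stream$state, envir = globalenv())
  expr
}
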