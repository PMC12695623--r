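# Seed handling: every stochastic stage takes an explicit seed, runs under a
# local RNG state, and restores the caller's state afterwards, so a single
# run-level seed makes whole pipelines byte-reproducible while leaving the
# user's session RNG untouched.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds: hash the run seed with a stage label (and an
# optional index) into [0, 2^31 - 2]. Stages can then be re-run in isolation
# with the same child seed the full pipeline used.
derive_seed <- function(seed, stage, index = 0L) {
  h <- vapply(paste(stage, index, sep = "#"), function(s) {
    acc <- as.numeric(seed) %% 2147483647
    for (ch in utf8ToInt(s)) acc <- (acc * 31 + ch) %% 2147483647
    acc
  }, numeric(1L), USE.NAMES = FALSE)
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
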