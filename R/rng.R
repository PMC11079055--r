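# Seeded local RNG streams. Generators take mandatory seeds and must not
# consume or clobber the caller's global RNG state, so each stream keeps
# its own .Random.seed and swaps it in only for the duration of a draw.

new_rng <- function(seed) {
  if (missing(seed) || !is.finite(seed)) stop("an explicit seed is required")
  env <- new.env(parent = emptyenv())
  with_state <- function(fn) {
    function(...) {
      old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
      if (is.null(env$state)) {
        set.seed(as.integer(seed))
      } else {
        assign(".Random.seed", env$state, envir = globalenv())
      }
      on.exit({
        env$state <- get(".Random.seed", envir = globalenv())
        if (is.null(old)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old, envir = globalenv())
        }
      })
      fn(...)
    }
  }
  list(
    rnorm = with_state(stats::rnorm),
    runif = with_state(stats::runif),
    sample = with_state(base::sample),
    sample_int = with_state(base::sample.int)
  )
}

# Derive a bounded child seed from a parent seed and a stage label so that
# pipeline stages get independent, reproducible streams (kept below 2^31).
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) *
             seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
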