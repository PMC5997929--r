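# Isolated RNG streams: draws are deterministic given the seed and never
# disturb the caller's .Random.seed.
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    if (is.null(state)) {
      set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
    out <- expr
    state <<- get(".Random.seed", globalenv(), inherits = FALSE)
    out
  }
  list(
    norm = function(n, mean = 0, sd = 1) with_state(rnorm(n, mean, sd)),
    unif = function(n, min = 0, max = 1) with_state(runif(n, min, max)),
    int = function(n, max) with_state(sample.int(max, n, replace = TRUE))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
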