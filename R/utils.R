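# Seed the RNG for the calling frame only: the caller's exit restores the
# global RNG state, so seeded package internals never perturb user code.
local_rng <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  set.seed(seed)
  invisible(NULL)
}

# half-up rounding to `digits` decimals (R's round() is banker's rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
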