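# Shared internal helpers.

# Display rounding is half-up (base round() is half-even, which disagrees
# with published money/percent figures on .5 boundaries).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Classed errors so callers (and the CLI exit-code mapping) can dispatch on
# failure kind rather than parse messages.
dd_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ddcea_error")))
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
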