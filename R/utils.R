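# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.  seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Smallest integer k with start + k * tick STRICTLY greater than `target`.
# The 1e-9 (in tick units) tolerance absorbs float noise so that an
# on-grid target maps to the next grid point, not to itself.
grid_index_after <- function(target, start, tick) {
  floor((target - start) / tick + 1e-9) + 1
}

# Number of whole ticks after which `t - ti > interval` first holds,
# i.e. smallest d with d * tick > interval.
ticks_strictly_over <- function(interval, tick) {
  floor(interval / tick + 1e-9) + 1
}

# Smallest d with d * tick >= interval (but at least 1): ticks a pulse
# must stay high before it may be lowered.
ticks_at_least <- function(interval, tick) {
  max(1L, as.integer(ceiling(interval / tick - 1e-9)))
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
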