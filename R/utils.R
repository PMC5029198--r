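# internal helpers shared across modules

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically derive `n` sub-seeds from a root seed (kept < 2^31).
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Toroidal wrap of coordinates into [0, extent)
wrap_position <- function(x, extent) x %% extent

# Minimum-image displacement on a torus of the given extent: maps raw
# frame-to-frame differences back into (-extent/2, extent/2].
unwrap_displacement <- function(d, extent) {
  ((d + extent / 2) %% extent) - extent / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
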