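# internal helpers

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive deterministic per-cell seeds from a master seed (splittable counter:
# one seeded draw stream, independent of how many cells are consumed later).
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("purkinje_invalid", "error")))
}

stop_infeasible <- function(...) {
  stop(errorCondition(paste0(...), class = c("purkinje_infeasible", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
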