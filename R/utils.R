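# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

l1_normalize <- function(x) {
  s <- sum(x)
  if (!is.finite(s) || s <= 0) {
    stop("cannot L1-normalize a vector with non-positive total mass")
  }
  x / s
}

# Evaluate `code` under a fixed RNG seed, then restore the caller's RNG state
# so library calls never perturb the session's random stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# sum-to-one check used by distribution invariants
sums_to_one <- function(x, tol = 1e-9) {
  abs(sum(x) - 1) <= tol
}
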