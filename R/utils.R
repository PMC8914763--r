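# Internal helpers shared across modules.

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream; seed = NULL runs expr on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# n sub-seeds derived deterministically from one master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# 2-D cross product (scalar z-component) of (r1,c1) x (r2,c2) pairs,
# computed in the (row, col) plane.
cross2 <- function(r1, c1, r2, c2) r1 * c2 - c1 * r2
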