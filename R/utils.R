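# misc internal helpers

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so protocol-internal randomness does not
#' disturb the caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# deterministic pseudo-random vectors keyed by (nonce, stream); used by the
# emulated backend for whitening and zero-sum decryption shares
prf_normal <- function(nonce, stream, len, sd = 1) {
  seed <- (as.numeric(nonce) * 48271 + stream * 16807 + 7) %% 2147483629
  with_seed(seed, rnorm(len, 0, sd))
}

prf_uniform <- function(nonce, stream, len, half_width) {
  seed <- (as.numeric(nonce) * 48271 + stream * 16807 + 7) %% 2147483629
  with_seed(seed, runif(len, -half_width, half_width))
}

fresh_nonce <- function() sample.int(2147483646L, 1L)

next_pow2 <- function(x) {
  stopifnot(x >= 1)
  2^ceiling(log2(x))
}

is_pow2 <- function(x) x >= 1 && abs(log2(x) - round(log2(x))) < 1e-12

#' Reset the homomorphic rotation counters
#'
#' The backend instruments rotations in three classes: `accumulation`
#' (shift-and-add rounds of row-row inner products), `replication` (doubling
#' rounds of encrypted row/column expansions) and `alignment` (hoisting a row
#' or column to the top of a block). Used by tests of the rotation budget.
#' @return invisibly, the zeroed counter vector
#' @export
reset_rotation_counts <- function() {
  .fhg$rotations <- c(accumulation = 0, replication = 0, alignment = 0)
  invisible(.fhg$rotations)
}

#' Read the homomorphic rotation counters
#' @return named numeric vector of rotation counts by class
#' @export
get_rotation_counts <- function() .fhg$rotations

count_rotation <- function(class) {
  .fhg$rotations[[class]] <- .fhg$rotations[[class]] + 1
}
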